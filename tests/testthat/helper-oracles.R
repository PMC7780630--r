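# Independent oracles used across the suite. Each is a deliberately naive
# reference implementation, kept independent of the package code paths.

# Naive O(n^3) Lance-Williams Ward agglomeration returning the cophenetic
# distance matrix (the tree's unique fingerprint for tie-free inputs).
# ward_d updates raw dissimilarities; ward_d2 squares first and reports
# square-rooted heights.
naive_ward_cophenetic <- function(d, variant = c("ward_d", "ward_d2")) {
  variant <- match.arg(variant)
  D <- as.matrix(d)
  n <- nrow(D)
  if (variant == "ward_d2") D <- D^2
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  diag(D) <- Inf
  while (length(members) > 1) {
    m <- nrow(D)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (D[i, j] < best[1] - 1e-12) best <- c(D[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    h <- if (variant == "ward_d2") sqrt(best[1]) else best[1]
    coph[members[[i]], members[[j]]] <- h
    coph[members[[j]], members[[i]]] <- h
    ni <- sizes[i]; nj <- sizes[j]
    upd <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(Inf)
      nk <- sizes[k]
      ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }, numeric(1))
    D[i, ] <- upd; D[, i] <- upd; D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
    members[[i]] <- c(members[[i]], members[[j]])
    members <- members[-j]
    sizes[i] <- ni + nj
    sizes <- sizes[-j]
  }
  coph
}

# Exhaustive hypergeometric enumeration for a 2x2 Fisher exact test.
fisher_enum_oracle <- function(tab, alternative = "two_sided") {
  a <- tab[1, 1]
  N <- sum(tab); K <- sum(tab[1, ]); n <- sum(tab[, 1])
  support <- max(0, K + n - N):min(K, n)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  switch(alternative,
    less = sum(probs[support <= a]),
    greater = sum(probs[support >= a]),
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hand-rolled two-group log-rank statistic (observed-minus-expected form).
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1); n <- sum(at_risk)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small deterministic beta-matrix fixture with annotation.
toy_beta_fixture <- function() {
  probes <- sprintf("p%02d", 1:10)
  samples <- c("s1", "s2", "s3")
  set.seed(11)
  beta <- matrix(runif(30), 10, 3, dimnames = list(probes, samples))
  beta["p04", "s2"] <- NA
  annotation <- data.frame(
    probe_id = probes,
    chrom = c("chr1", "chr2", "chrX", "chr3", "chrX", "chr4", "chr5",
              "chr6", "chr7", "chr8"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L),
    gene = c("GA", "GA", "GB", "GB", "GC", "GC", "GD", "", "GE", "GE"),
    promoter_class = c("TSS200", "TSS1500", "Body", "1stExon", "5'UTR",
                       "Body", "TSS200", "IGR", "3'UTR", "TSS200"),
    cgi_relation = rep(c("island", "shore"), 5),
    enhancer_flag = rep(c(TRUE, FALSE), each = 5),
    dnase_flag = rep(c(FALSE, TRUE), 5),
    stringsAsFactors = FALSE)
  list(beta = beta, annotation = annotation)
}

# Two-block beta matrix with an obvious sample split, for consensus tests.
two_blob_beta <- function(n_probes = 40, n_per_group = 6, seed = 5) {
  set.seed(seed)
  g1 <- matrix(rbeta(n_probes * n_per_group, 8, 2), n_probes)
  g2 <- matrix(rbeta(n_probes * n_per_group, 2, 8), n_probes)
  x <- cbind(g1, g2)
  dimnames(x) <- list(sprintf("p%03d", seq_len(n_probes)),
                      sprintf("s%02d", seq_len(2 * n_per_group)))
  x
}
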