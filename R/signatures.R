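#' The 96 pyrimidine-centric single-base-substitution channels
#'
#' Channel order is the community convention: the six pyrimidine
#' substitutions C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the 16
#' flanking-base contexts in alphabetical order (5' base A,C,G,T crossed
#' with 3' base A,C,G,T). Channel names look like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t) paste0(f, "[", s, "]", t))))
  }))
}

.check_basis <- function(basis) {
  if (!is.matrix(basis) || nrow(basis) != 96) {
    stop("signature basis must be a 96 x S matrix", call. = FALSE)
  }
  if (any(basis < 0)) stop("signature basis must be non-negative", call. = FALSE)
  s <- colSums(basis)
  if (any(abs(s - 1) > 1e-6)) {
    stop("basis columns must sum to 1 within 1e-6", call. = FALSE)
  }
  invisible(basis)
}

#' Generate a synthetic sparse signature basis
#'
#' Columns are sparse random profiles over the 96 channels (normalized
#' gamma draws with a small shape parameter), giving well-separated
#' synthetic signatures suitable for exposure-recovery experiments.
#' Deterministic given the seed.
#'
#' @param n_signatures Number of columns.
#' @param shape Gamma shape controlling sparsity (smaller = sparser).
#' @param seed Integer seed.
#' @return 96 x n_signatures column-stochastic matrix with channel row
#'   names and columns `SigS1`, `SigS2`, ...
#' @export
synthetic_signature_basis <- function(n_signatures = 5L, shape = 0.15,
                                      seed = 42L) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(96 * n_signatures, shape = shape), 96)
    m <- sweep(m, 2, colSums(m), "/")
    dimnames(m) <- list(sbs96_channels(), paste0("SigS", seq_len(n_signatures)))
    m
  })
}

#' Build a 96-channel mutation catalog
#'
#' Keeps coding single-base substitutions (classes missense, silent,
#' nonsense, with single-base A/C/G/T ref and alt and a 3-mer context);
#' indels and multi-base events are excluded. Purine-reference records are
#' reverse-complemented onto the pyrimidine strand before binning. A
#' context whose center base disagrees with the record's ref is an error.
#'
#' @param records Mutation records (from [parse_mutations()] or the
#'   simulator).
#' @param sample_universe All cohort samples (zero-SNV samples get all-zero
#'   rows).
#' @return Integer count matrix, samples x 96 channels.
#' @export
build_catalog <- function(records, sample_universe) {
  channels <- sbs96_channels()
  cat <- matrix(0L, length(sample_universe), 96,
                dimnames = list(sample_universe, channels))
  bases <- c("A", "C", "G", "T")
  snv <- records$variant_class %in% c("missense", "silent", "nonsense") &
    records$ref %in% bases & records$alt %in% bases &
    records$ref != records$alt & nchar(records$context) == 3
  r <- records[snv, , drop = FALSE]
  if (nrow(r) == 0) return(cat)
  if (any(substr(r$context, 2, 2) != r$ref)) {
    stop("context center base does not match ref for some records")
  }
  purine <- r$ref %in% c("A", "G")
  ref <- ifelse(purine, chartr("ACGT", "TGCA", r$ref), r$ref)
  alt <- ifelse(purine, chartr("ACGT", "TGCA", r$alt), r$alt)
  ctx <- ifelse(purine, .revcomp(r$context), r$context)
  chan <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  keep <- r$sample_id %in% sample_universe
  tab <- table(factor(r$sample_id[keep], levels = sample_universe),
               factor(chan[keep], levels = channels))
  cat[, ] <- as.integer(tab)
  cat
}

# NNLS fit of f against the selected basis columns; returns weights + SSE
.nnls_fit <- function(B, f) {
  fit <- pracma::lsqnonneg(B, f)
  w <- fit$x
  err <- sum((f - B %*% w)^2)
  list(w = w, err = err)
}

#' Fit per-sample signature exposures by forward selection
#'
#' For each sample the 96-channel counts are converted to frequencies,
#' optionally re-weighted by a per-channel normalization vector (e.g. an
#' exome-to-genome trinucleotide-frequency correction) and renormalized.
#' Signatures are then added greedily: each step adds the signature giving
#' the largest reduction in the sum-of-squares between the reconstructed
#' and observed frequency vector, jointly refitting the retained weights
#' by non-negative least squares, and stops when the improvement falls
#' below 1e-4. Fitted weights below `cutoff` are zeroed and the remainder
#' refit once; weights still below the cutoff after that refit are zeroed
#' without further refitting, so every reported nonzero weight is at least
#' `cutoff`. The per-sample residual weight is `1 - sum(weights)` and
#' represents the unexplained ("unknown") share, which downstream
#' clustering discards.
#'
#' @param catalog Samples x 96 count matrix from [build_catalog()].
#' @param basis 96 x S column-stochastic signature basis.
#' @param cutoff Minimum reportable exposure weight (default 0.2).
#' @param normalization Optional positive 96-vector of per-channel weights;
#'   NULL means identity (appropriate when catalog and basis share the
#'   same trinucleotide background, as in the synthetic cohorts).
#' @return List with `exposures` (samples x S), `residual` (per-sample),
#'   and `skipped` (ids of zero-mutation samples, which are left out with a
#'   warning).
#' @export
fit_exposures <- function(catalog, basis, cutoff = 0.2, normalization = NULL) {
  .check_basis(basis)
  if (ncol(catalog) != 96 || !identical(colnames(catalog), rownames(basis))) {
    stop("catalog channels do not match the basis channel order")
  }
  if (!is.null(normalization)) {
    if (length(normalization) != 96 || any(normalization <= 0)) {
      stop("normalization must be a positive 96-vector")
    }
  }
  S <- ncol(basis)
  n <- nrow(catalog)
  expo <- matrix(0, n, S, dimnames = list(rownames(catalog), colnames(basis)))
  totals <- rowSums(catalog)
  skipped <- rownames(catalog)[totals == 0]
  if (length(skipped)) {
    warning("samples with zero mutations skipped: ",
            paste(skipped, collapse = ", "))
  }
  for (i in which(totals > 0)) {
    f <- catalog[i, ] / totals[i]
    if (!is.null(normalization)) {
      f <- f * normalization
      f <- f / sum(f)
    }
    sel <- integer()
    err <- sum(f^2)
    w_sel <- numeric()
    repeat {
      cand <- setdiff(seq_len(S), sel)
      if (!length(cand)) break
      best <- NULL
      for (j in cand) {
        fit <- .nnls_fit(basis[, c(sel, j), drop = FALSE], f)
        if (is.null(best) || fit$err < best$err) best <- c(fit, j = j)
      }
      if (err - best$err < 1e-4) break
      sel <- c(sel, best$j)
      w_sel <- best$w
      err <- best$err
    }
    w <- numeric(S)
    w[sel] <- w_sel
    if (sum(w) > 1) w <- w / sum(w)
    low <- w > 0 & w < cutoff
    if (any(low)) {
      w[low] <- 0
      keep <- which(w > 0)
      if (length(keep)) {
        refit <- .nnls_fit(basis[, keep, drop = FALSE], f)
        w[keep] <- refit$w
        if (sum(w) > 1) w <- w / sum(w)
        w[w < cutoff] <- 0
      }
    }
    expo[i, ] <- w
  }
  list(exposures = expo, residual = 1 - rowSums(expo), skipped = skipped)
}

#' NMF clustering of an exposure matrix (multiplicative updates)
#'
#' Factorizes the signatures x samples exposure matrix as `V ~ W %*% H`
#' under squared Frobenius loss with Lee-Seung multiplicative updates, the
#' conventional definition of the "lee" method. The best of `n_restarts`
#' random initialisations (by final loss) is kept; the loss trace of each
#' run is non-increasing. Each sample is assigned to the factor with the
#' maximal coefficient in its column of `H`.
#'
#' @param exposures Samples x S non-negative exposure matrix (the residual
#'   weight is not part of it).
#' @param rank Factorization rank (default 3).
#' @param n_restarts Random restarts (default 30).
#' @param max_iter Maximum update iterations per run (default 2000).
#' @param tol Relative loss-improvement convergence tolerance (default 1e-6).
#' @param seed Integer seed; results are deterministic given it.
#' @return `nmf_result` list: `W` (S x rank), `H` (rank x n), `rank`,
#'   `labels` (named factor index per sample), `restart_losses`,
#'   `loss_trace` (best run), `seed`.
#' @export
nmf_cluster <- function(exposures, rank = 3L, n_restarts = 30L,
                        max_iter = 2000L, tol = 1e-6, seed = 1L) {
  V <- t(exposures)
  if (any(V < 0)) stop("exposures must be non-negative")
  if (rank > min(dim(V))) stop("rank exceeds matrix dimensions")
  if (ncol(V) < rank) stop("need at least `rank` samples")
  eps <- .Machine$double.eps
  best <- NULL
  losses <- numeric(n_restarts)
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      W <- matrix(stats::runif(nrow(V) * rank, 0.1, 1), nrow(V), rank)
      H <- matrix(stats::runif(rank * ncol(V), 0.1, 1), rank, ncol(V))
      trace <- numeric()
      prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
        W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
        loss <- sum((V - W %*% H)^2)
        trace <- c(trace, loss)
        if (is.finite(prev) && (prev - loss) <= tol * max(prev, eps)) break
        prev <- loss
      }
      losses[r] <- loss
      if (is.null(best) || loss < best$loss) {
        best <- list(W = W, H = H, loss = loss, trace = trace)
      }
    }
  })
  labels <- apply(best$H, 2, which.max)  # ties resolve to the lowest index
  names(labels) <- rownames(exposures)
  dimnames(best$W) <- list(colnames(exposures), paste0("F", seq_len(rank)))
  dimnames(best$H) <- list(paste0("F", seq_len(rank)), rownames(exposures))
  structure(list(W = best$W, H = best$H, rank = as.integer(rank),
                 labels = labels, restart_losses = losses,
                 loss_trace = best$trace, seed = as.integer(seed)),
            class = "nmf_result")
}

#' Map signatures to the NMF factor they contribute most to
#'
#' Each signature is assigned to the factor where its basis loading in `W`
#' is maximal ("max" contributor extraction); ties resolve to the lowest
#' factor index.
#'
#' @param result An `nmf_result` from [nmf_cluster()].
#' @return Named integer vector, signature -> factor index.
#' @export
extract_contributors <- function(result) {
  stopifnot(inherits(result, "nmf_result"))
  contrib <- apply(result$W, 1, which.max)
  stats::setNames(as.integer(contrib), rownames(result$W))
}
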