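#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-values via [stats::fisher.test()]; the two-sided
#' p is the probability-mass definition (sum of table probabilities not
#' exceeding the observed one, with 1e-7 relative slack). The reported odds
#' ratio is the sample OR with Haldane 0.5 correction on zero cells, not
#' the conditional MLE. A table with an all-zero margin gets p = 1 and an
#' undefined-OR flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return List with `p_value`, `odds_ratio`, `log2_odds_ratio`,
#'   `or_undefined`.
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_,
                log2_odds_ratio = NA_real_, or_undefined = TRUE))
  }
  alt <- c(two_sided = "two.sided", less = "less", greater = "greater")[alternative]
  p <- stats::fisher.test(table, alternative = alt)$p.value
  or <- .sample_or(table)
  list(p_value = min(p, 1), odds_ratio = or, log2_odds_ratio = log2(or),
       or_undefined = FALSE)
}

# exact Mann-Whitney null by enumeration of group assignments (tie-aware)
.mw_exact <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  u_null <- apply(combos, 2, u_of)
  tolr <- 1e-9
  switch(alternative,
    less = mean(u_null <= u_obs + tolr),
    greater = mean(u_null >= u_obs - tolr),
    two_sided = {
      mu <- nx * ny / 2
      min(1, mean(abs(u_null - mu) >= abs(u_obs - mu) - tolr))
    })
}

#' Mann-Whitney U test
#'
#' Exact enumeration of all group assignments (correct under ties) when
#' both samples have at most 8 observations; otherwise the tie-corrected
#' normal approximation of [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (on x
#'   relative to y).
#' @return List with `U` (statistic of x), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (max(length(x), length(y)) <= 8) {
    p <- .mw_exact(x, y, alternative)
    method <- "exact enumeration"
  } else {
    alt <- c(two_sided = "two.sided", less = "less", greater = "greater")[alternative]
    p <- stats::wilcox.test(x, y, alternative = alt, exact = FALSE,
                            correct = FALSE)$p.value
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = p, method = method)
}

#' Benjamini-Hochberg adjusted p-values
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(p) {
  .check_prob(p[!is.na(p)], "p")
  stats::p.adjust(p, method = "BH")
}

.surv_endpoint <- function(clinical, endpoint) {
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical))) {
    stop("clinical table lacks ", tcol, "/", ecol)
  }
  if (any(clinical[[tcol]] < 0)) stop("survival times must be >= 0")
  survival::Surv(clinical[[tcol]], as.integer(clinical[[ecol]]))
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit estimates per group and the log-rank chi-square via
#' the survival package. A cohort with no events is flagged degenerate
#' (the log-rank statistic is undefined) rather than tested.
#'
#' @param clinical data.frame with `<endpoint>_time` / `<endpoint>_event`.
#' @param groups Group assignment, one per row (no empty groups).
#' @param endpoint `"os"` or `"pfs"`.
#' @return List with `fit` (survfit object), `chisq`, `df`, `p_value`,
#'   `degenerate`.
#' @export
km_logrank <- function(clinical, groups, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("every group needs at least one subject")
  s <- .surv_endpoint(clinical, endpoint)
  fit <- survival::survfit(s ~ groups)
  if (sum(clinical[[paste0(endpoint, "_event")]]) == 0) {
    return(list(fit = fit, chisq = NA_real_, df = nlevels(groups) - 1L,
                p_value = NA_real_, degenerate = TRUE))
  }
  sd <- survival::survdiff(s ~ groups)
  df <- nlevels(groups) - 1L
  list(fit = fit, chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with Breslow tie handling
#' by default (Efron selectable). Monotone likelihood (complete separation,
#' e.g. all events in one group with no overlap) is flagged and no estimate
#' is reported.
#'
#' @param clinical data.frame with `<endpoint>_time` / `<endpoint>_event`.
#' @param covariate Vector (numeric or 2+-level factor), one per row; must
#'   vary.
#' @param endpoint `"os"` or `"pfs"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List with `log_hr`, `hr`, `ci_lower`, `ci_upper`, `se`,
#'   `p_value`, `separated`.
#' @export
cox_univariate <- function(clinical, covariate, endpoint = c("os", "pfs"),
                           ties = c("breslow", "efron")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  if (length(unique(covariate)) < 2) stop("covariate does not vary")
  s <- .surv_endpoint(clinical, endpoint)
  separated <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(s ~ covariate, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coef <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  if (separated || !is.finite(coef) || abs(coef) > 15) {
    return(list(log_hr = NA_real_, hr = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, se = NA_real_, p_value = NA_real_,
                separated = TRUE))
  }
  list(log_hr = coef, hr = exp(coef),
       ci_lower = exp(coef - 1.96 * se), ci_upper = exp(coef + 1.96 * se),
       se = se, p_value = 2 * stats::pnorm(-abs(coef / se)),
       separated = FALSE)
}

#' Expression filtering and normalization for clustering
#'
#' Drops genes whose FPKM is below `min_fpkm` in at least `min_fraction`
#' of samples, then log2(x + 1)-transforms and median-centers rows and
#' columns (the default order; a center-first variant using a signed log
#' is selectable, since centering raw FPKM produces negative values that a
#' plain log cannot take).
#'
#' @param fpkm Genes x samples non-negative expression matrix.
#' @param min_fpkm Low-expression threshold (default 1).
#' @param min_fraction Fraction of samples allowed below it (default 0.9,
#'   `>=` semantics: a gene low in exactly 90% of samples is dropped).
#' @param transform_order `"log2_then_center"` (default) or
#'   `"center_then_log2"`.
#' @return Filtered, transformed matrix.
#' @export
expression_filter <- function(fpkm, min_fpkm = 1, min_fraction = 0.9,
                              transform_order = c("log2_then_center",
                                                  "center_then_log2")) {
  transform_order <- match.arg(transform_order)
  if (any(fpkm < 0)) stop("FPKM values must be >= 0")
  low <- rowMeans(fpkm < min_fpkm)
  x <- fpkm[low < min_fraction, , drop = FALSE]
  center <- function(m) {
    m <- m - apply(m, 1, stats::median)
    m - rep(apply(m, 2, stats::median), each = nrow(m))
  }
  if (transform_order == "log2_then_center") {
    center(log2(x + 1))
  } else {
    m <- center(x)
    sign(m) * log2(1 + abs(m))
  }
}

#' Nearest-centroid expression classifier
#'
#' Assigns each sample the class whose centroid profile has the highest
#' Pearson correlation with the sample over the shared gene set. Ties
#' resolve to the lowest class index with a warning; zero-variance samples
#' are left unclassified.
#'
#' @param expression Genes x samples matrix.
#' @param centroids Genes x classes matrix of class centroids.
#' @return data.frame with sample_id, label (NA when unclassified),
#'   best_cor; the full sample x class correlation matrix is attached as
#'   attribute `correlations`.
#' @export
nearest_centroid_classify <- function(expression, centroids) {
  shared <- intersect(rownames(expression), rownames(centroids))
  if (length(shared) < 2) stop("need at least 2 shared genes with the centroids")
  e <- expression[shared, , drop = FALSE]
  ce <- centroids[shared, , drop = FALSE]
  cors <- suppressWarnings(stats::cor(e, ce))
  labels <- character(ncol(e))
  best <- numeric(ncol(e))
  for (i in seq_len(ncol(e))) {
    if (stats::sd(e[, i]) == 0 || all(is.na(cors[i, ]))) {
      labels[i] <- NA_character_
      best[i] <- NA_real_
      next
    }
    ci <- cors[i, ]
    top <- which(ci == max(ci, na.rm = TRUE))
    if (length(top) > 1) warning("correlation tie for sample ", colnames(e)[i],
                                 "; lowest class index used")
    labels[i] <- colnames(ce)[top[1]]
    best[i] <- ci[top[1]]
  }
  out <- data.frame(sample_id = colnames(e), label = labels, best_cor = best,
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- cors
  out
}

#' Single-sample gene-set signature score
#'
#' `mean_z`: the mean across the gene set of per-gene z-scores (computed
#' across samples). `rank_ssgsea`: a weighted Kolmogorov-Smirnov running
#' sum over each sample's within-sample expression ranks — genes are walked
#' in decreasing rank, in-set steps weighted by rank^0.25 (normalized to
#' sum 1), out-of-set steps uniform, and the score is the running-sum
#' integral divided by the number of genes.
#'
#' @param expression Genes x samples matrix.
#' @param gene_set Character vector; its intersection with the gene
#'   universe must be non-empty.
#' @param method `"mean_z"` or `"rank_ssgsea"`.
#' @param alpha Rank-weight exponent for `rank_ssgsea` (default 0.25).
#' @return Named per-sample score vector.
#' @export
signature_score <- function(expression, gene_set,
                            method = c("mean_z", "rank_ssgsea"), alpha = 0.25) {
  method <- match.arg(method)
  genes <- intersect(rownames(expression), gene_set)
  if (!length(genes)) stop("gene_set does not intersect the expression universe")
  if (method == "mean_z") {
    mu <- rowMeans(expression)
    sdv <- apply(expression, 1, stats::sd)
    z <- (expression - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    return(colMeans(z[genes, , drop = FALSE]))
  }
  n <- nrow(expression)
  in_set <- rownames(expression) %in% genes
  scores <- apply(expression, 2, function(v) {
    r <- rank(v, ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    hits <- in_set[ord]
    w <- r[ord]^alpha * hits
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hits) / sum(!hits)
    sum(p_in - p_out) / n
  })
  stats::setNames(scores, colnames(expression))
}
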