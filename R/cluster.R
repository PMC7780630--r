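#' Agglomerative clustering with Ward linkage on a precomputed dissimilarity
#'
#' Thin validated front end over [stats::hclust()] exposing the two
#' conventional Ward variants: `ward_d` applies the Lance-Williams Ward
#' update to the dissimilarities as given, while `ward_d2` squares them
#' before updating and reports square-rooted merge heights. Both accept any
#' symmetric non-negative dissimilarity (Euclidean, Manhattan, 1 - Pearson).
#'
#' @param dissimilarity Symmetric numeric matrix with zero diagonal, or a
#'   `dist` object.
#' @param linkage `"ward_d"` or `"ward_d2"`.
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(dissimilarity, linkage = c("ward_d", "ward_d2")) {
  linkage <- match.arg(linkage)
  if (!inherits(dissimilarity, "dist")) {
    if (!is.matrix(dissimilarity) || nrow(dissimilarity) != ncol(dissimilarity)) {
      stop("dissimilarity must be square or a 'dist' object")
    }
    if (max(abs(dissimilarity - t(dissimilarity))) > 1e-8) {
      stop("dissimilarity matrix is not symmetric")
    }
    if (any(dissimilarity < -1e-12)) stop("dissimilarities must be non-negative")
    dissimilarity <- stats::as.dist(dissimilarity)
  }
  method <- if (linkage == "ward_d") "ward.D" else "ward.D2"
  stats::hclust(dissimilarity, method = method)
}

#' Consensus clustering parameters
#'
#' Defaults encode the resampling protocol used for supervised methylation
#' clustering: 500 perturbations each drawing 80% of samples and 80% of
#' features, Manhattan distance with Ward (D2) linkage on the subsamples,
#' and a final cut of the consensus matrix using 1 - Pearson distance with
#' Ward (D2) linkage.
#'
#' @param n_runs Number of resampling runs (>= 1).
#' @param sample_fraction,feature_fraction Fractions in (0, 1] resampled
#'   without replacement per run.
#' @param base_distance,final_distance One of `"euclidean"`, `"manhattan"`,
#'   `"one_minus_pearson"`.
#' @param base_linkage,final_linkage `"ward_d"` or `"ward_d2"`.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A validated `consensus_params` list.
#' @export
consensus_params <- function(n_runs = 500L, sample_fraction = 0.8,
                             feature_fraction = 0.8,
                             base_distance = c("manhattan", "euclidean", "one_minus_pearson"),
                             base_linkage = c("ward_d2", "ward_d"),
                             final_distance = c("one_minus_pearson", "euclidean", "manhattan"),
                             final_linkage = c("ward_d2", "ward_d"),
                             k = 2L, seed = 1L) {
  base_distance <- match.arg(base_distance)
  final_distance <- match.arg(final_distance)
  base_linkage <- match.arg(base_linkage)
  final_linkage <- match.arg(final_linkage)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (sample_fraction <= 0 || sample_fraction > 1 ||
      feature_fraction <= 0 || feature_fraction > 1) {
    stop("resampling fractions must lie in (0, 1]")
  }
  if (k < 2) stop("k must be >= 2")
  structure(list(n_runs = as.integer(n_runs), sample_fraction = sample_fraction,
                 feature_fraction = feature_fraction, base_distance = base_distance,
                 base_linkage = base_linkage, final_distance = final_distance,
                 final_linkage = final_linkage, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "consensus_params")
}

# pairwise sample dissimilarity; x is features x samples
.pair_distance <- function(x, distance) {
  switch(distance,
    euclidean = stats::dist(t(x), method = "euclidean"),
    manhattan = stats::dist(t(x), method = "manhattan"),
    one_minus_pearson = stats::as.dist(1 - stats::cor(x)),
    stop("unknown distance: ", distance))
}

#' Consensus clustering by resampled hierarchical clustering
#'
#' Repeatedly subsamples samples and features without replacement, clusters
#' each subsample by hierarchical clustering cut at `k`, and accumulates a
#' connectivity count for every co-sampled pair that lands in the same
#' cluster. The consensus entry for a pair is its co-cluster count divided
#' by its co-sample count (pairs never drawn together get consensus 0 with a
#' warning). Final labels come from hierarchical clustering of the
#' consensus matrix rows under `final_distance`/`final_linkage`, cut at `k`.
#'
#' @param x Numeric matrix, features in rows and samples in columns; no
#'   missing values.
#' @param params A [consensus_params()] object.
#' @return A `consensus_result`: list with `consensus` (n x n in `[0, 1]`),
#'   `cosample_counts`, `labels` (named integer vector), `params` and
#'   `skipped_runs`.
#' @export
consensus_cluster <- function(x, params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  if (anyNA(x)) stop("feature matrix must not contain missing values")
  n <- ncol(x)
  if (n < 2L * params$k) stop("need at least 2*k samples")
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))

  conn <- matrix(0, n, n)
  cosamp <- matrix(0L, n, n)
  n_s <- max(1L, floor(params$sample_fraction * n))
  n_f <- max(1L, floor(params$feature_fraction * nrow(x)))
  skipped <- 0L

  withr::with_seed(params$seed, {
    for (run in seq_len(params$n_runs)) {
      samp <- sort(sample.int(n, n_s))
      feat <- sort(sample.int(nrow(x), n_f))
      if (length(samp) < params$k) {
        warning("run ", run, " drew fewer than k samples; skipped")
        skipped <- skipped + 1L
        next
      }
      d <- .pair_distance(x[feat, samp, drop = FALSE], params$base_distance)
      hc <- hierarchical_cluster(d, params$base_linkage)
      lab <- stats::cutree(hc, k = params$k)
      co <- outer(lab, lab, "==")
      conn[samp, samp] <- conn[samp, samp] + co
      cosamp[samp, samp] <- cosamp[samp, samp] + 1L
    }
  })

  consensus <- matrix(0, n, n)
  seen <- cosamp > 0
  consensus[seen] <- conn[seen] / cosamp[seen]
  off <- !seen & upper.tri(cosamp)
  if (any(off)) {
    warning(sum(off), " sample pair(s) were never co-sampled; consensus set to 0")
  }
  dimnames(consensus) <- dimnames(cosamp) <- list(ids, ids)

  fd <- .pair_distance(t(consensus), params$final_distance)
  labels <- stats::cutree(hierarchical_cluster(fd, params$final_linkage),
                          k = params$k)
  names(labels) <- ids

  structure(list(consensus = consensus, cosample_counts = cosamp,
                 labels = labels, params = params, skipped_runs = skipped),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering result\n")
  cat("  samples:", ncol(x$consensus), " k:", x$params$k,
      " runs:", x$params$n_runs, "(", x$skipped_runs, "skipped )\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' Supervised clustering of an external cohort on a probe signature
#'
#' Restricts the external beta matrix to the probes it shares with a derived
#' hypermethylation signature and runs consensus clustering with the
#' supervised defaults (Manhattan/Ward.D2 base runs; 1 - Pearson/Ward.D2 on
#' the consensus matrix). Used to transfer a two-subtype methylome signature
#' onto an independent cohort profiled on a different array.
#'
#' @param external Probes x samples beta matrix of the external cohort.
#' @param signature Character vector of signature probe ids.
#' @param params Optional [consensus_params()]; supervised defaults if NULL.
#' @return A `consensus_result` with an extra `n_intersect` element.
#' @export
transfer_signature <- function(external, signature, params = NULL) {
  .check_beta_matrix(external)
  if (!length(signature)) stop("signature probe set is empty")
  shared <- intersect(rownames(external), signature)
  if (!length(shared)) {
    stop("signature does not intersect the external probe universe; transfer impossible")
  }
  if (is.null(params)) params <- consensus_params()
  res <- consensus_cluster(external[shared, , drop = FALSE], params)
  res$n_intersect <- length(shared)
  res
}
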