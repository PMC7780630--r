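#' Probe-level quality filtering of a beta matrix
#'
#' Removes probes on the sex chromosomes, probes with at least one missing
#' value, and (when a detection p-value matrix is supplied) probes that fail
#' detection in any sample. The order of surviving probes is preserved.
#'
#' @param beta Probes x samples beta matrix.
#' @param annotation Probe annotation data.frame covering every probe.
#' @param drop_sex Remove probes annotated to chrX/chrY.
#' @param drop_missing Remove probes with >= 1 missing beta value.
#' @param detection_p Optional matrix of detection p-values, same dimnames
#'   as `beta`; probes with any value above `p_cutoff` are removed.
#' @param p_cutoff Detection p-value cutoff (default 0.05).
#' @return The filtered beta matrix.
#' @export
filter_probes <- function(beta, annotation, drop_sex = TRUE, drop_missing = TRUE,
                          detection_p = NULL, p_cutoff = 0.05) {
  .check_beta_matrix(beta)
  .check_annotation(annotation)
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  if (anyNA(ann$probe_id)) {
    stop("annotation missing for probes: ",
         paste(utils::head(setdiff(rownames(beta), annotation$probe_id), 5),
               collapse = ", "))
  }
  bad <- !(ann$chrom %in% .valid_chroms())
  if (any(bad)) {
    stop("unknown chromosome names: ",
         paste(unique(ann$chrom[bad]), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(beta))
  if (drop_sex) keep <- keep & !.is_sex_chrom(ann$chrom)
  if (drop_missing) keep <- keep & !apply(is.na(beta), 1, any)
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta))) {
      stop("detection_p must match the dimensions of beta")
    }
    keep <- keep & apply(detection_p <= p_cutoff, 1, all)
  }
  beta[keep, , drop = FALSE]
}

#' Select the most variable probes
#'
#' Ranks probes by a variability metric and returns the top
#' `floor(fraction * n_probes)` ids. Ties are broken by lexicographic probe
#' id so the selection is deterministic across platforms.
#'
#' @param beta Probes x samples beta matrix without missing values (run
#'   [filter_probes()] first).
#' @param fraction Fraction of probes to keep, in (0, 1]; default 0.01
#'   ("top 1%").
#' @param metric `"variance"` (default), `"sd"` or `"mad"`.
#' @return Character vector of selected probe ids.
#' @export
select_variable_probes <- function(beta, fraction = 0.01,
                                   metric = c("variance", "sd", "mad")) {
  metric <- match.arg(metric)
  if (anyNA(beta)) stop("beta must not contain missing values")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  score <- switch(metric,
    variance = apply(beta, 1, stats::var),
    sd = apply(beta, 1, stats::sd),
    mad = apply(beta, 1, stats::mad))
  n_keep <- floor(fraction * nrow(beta))
  ord <- order(-score, rownames(beta))
  rownames(beta)[ord][seq_len(n_keep)]
}

# vectorized two-sample Welch t-test across matrix rows
.row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # probes constant in both groups carry no evidence: p = 1 by convention
  flat <- (v1 + v2) == 0
  p[flat] <- 1
  t[flat] <- 0
  list(t = t, p = p)
}

#' Differentially methylated probe (DMP) testing between two groups
#'
#' Per-probe two-sided unequal-variance (Welch) test between the two label
#' groups, by default on M-values `log2(beta / (1 - beta))` with beta
#' clipped to `[1e-3, 1 - 1e-3]` to stabilise variance near the bounds.
#' Group means and the effect size delta are always reported on the beta
#' scale. P-values are Benjamini-Hochberg adjusted across all tested probes
#' in a single pass; a probe is flagged `significant` when
#' `|delta| >= delta_cutoff` and `fdr < fdr_cutoff`.
#'
#' @param beta Probes x samples beta matrix without missing values.
#' @param labels Two-group assignment (vector coercible to factor, one
#'   entry per sample; both groups need >= 2 samples). Group 1 is the first
#'   factor level.
#' @param test_space `"m_value"` (default) or `"beta"`.
#' @param delta_cutoff Minimum |delta beta| for significance (default 0.2).
#' @param fdr_cutoff BH FDR threshold (default 0.05).
#' @return data.frame with probe_id, mean_beta_g1, mean_beta_g2, delta,
#'   p_value, fdr, significant, and hyper_call (the 0.4 / 0.2 / FDR < 0.05
#'   hypermethylation rule evaluated for group 1; see
#'   [derive_hyper_signature()] for the tunable version).
#' @export
call_dmps <- function(beta, labels, test_space = c("m_value", "beta"),
                      delta_cutoff = 0.2, fdr_cutoff = 0.05) {
  test_space <- match.arg(test_space)
  if (anyNA(beta)) stop("beta must not contain missing values")
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must define exactly two groups")
  if (length(labels) != ncol(beta)) stop("one label per sample required")
  if (any(table(labels) < 2L)) stop("both groups need at least 2 samples")

  g1 <- labels == levels(labels)[1]
  x <- beta
  if (test_space == "m_value") {
    eps <- 1e-3
    x <- pmin(pmax(beta, eps), 1 - eps)
    x <- log2(x / (1 - x))
  }
  tt <- .row_welch(x[, g1, drop = FALSE], x[, !g1, drop = FALSE])
  mb1 <- rowMeans(beta[, g1, drop = FALSE])
  mb2 <- rowMeans(beta[, !g1, drop = FALSE])
  fdr <- stats::p.adjust(tt$p, method = "BH")
  data.frame(
    probe_id = rownames(beta),
    mean_beta_g1 = mb1, mean_beta_g2 = mb2, delta = mb1 - mb2,
    p_value = tt$p, fdr = fdr,
    significant = abs(mb1 - mb2) >= delta_cutoff & fdr < fdr_cutoff,
    hyper_call = mb1 >= 0.4 & mb2 <= 0.2 & fdr < 0.05,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypermethylation signature rule
#'
#' A probe is called significantly hypermethylated in group 1 when its mean
#' beta in group 1 is at least `hyper_mean` (default 0.4), its mean beta in
#' group 2 is at most `hypo_mean` (default 0.2), and the probe's BH FDR is
#' below `fdr_cutoff` (default 0.05). The rule is applied symmetrically with
#' the group roles swapped to obtain the probes hypermethylated in group 2.
#'
#' @param dmps DMP table from [call_dmps()].
#' @param hyper_mean Minimum mean beta in the hypermethylated group.
#' @param hypo_mean Maximum mean beta in the other group.
#' @param fdr_cutoff BH FDR threshold.
#' @return List with `hyper_in_g1` and `hyper_in_g2` probe-id vectors.
#' @export
derive_hyper_signature <- function(dmps, hyper_mean = 0.4, hypo_mean = 0.2,
                                   fdr_cutoff = 0.05) {
  sig <- dmps$fdr < fdr_cutoff
  list(
    hyper_in_g1 = dmps$probe_id[sig & dmps$mean_beta_g1 >= hyper_mean &
                                  dmps$mean_beta_g2 <= hypo_mean],
    hyper_in_g2 = dmps$probe_id[sig & dmps$mean_beta_g2 >= hyper_mean &
                                  dmps$mean_beta_g1 <= hypo_mean])
}

#' Proximity-merge DMR calling
#'
#' Merges significant same-direction probes on the same chromosome into
#' regions whenever consecutive probes are at most `max_gap_bp` apart, and
#' reports regions with at least `min_probes` probes. This is a declared
#' gap-merge caller, not a kernel-smoothed one; the rule is recorded in the
#' output's `caller` attribute so results are never confused with smoothed
#' DMR output. Emitted spans are BED-style 0-based half-open.
#'
#' @param dmps DMP table from [call_dmps()].
#' @param annotation Probe annotation providing chrom/pos.
#' @param max_gap_bp Maximum gap between consecutive probes (default 1000).
#' @param min_probes Minimum probes per reported region (default 2).
#' @return data.frame with chrom, start, end, n_probes, mean_delta,
#'   direction.
#' @export
call_dmrs <- function(dmps, annotation, max_gap_bp = 1000L, min_probes = 2L) {
  .check_annotation(annotation)
  sig <- dmps[dmps$significant, , drop = FALSE]
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_probes = integer(), mean_delta = double(),
                    direction = character(), stringsAsFactors = FALSE)
  if (nrow(sig)) {
    idx <- match(sig$probe_id, annotation$probe_id)
    if (anyNA(idx)) stop("significant probes missing from annotation")
    sig$chrom <- annotation$chrom[idx]
    sig$pos <- annotation$pos[idx]
    sig$direction <- ifelse(sig$delta > 0, "hyper", "hypo")
    pieces <- split(sig, list(sig$chrom, sig$direction), drop = TRUE)
    regions <- lapply(pieces, function(d) {
      d <- d[order(d$pos), ]
      grp <- cumsum(c(0L, diff(d$pos) > max_gap_bp))
      do.call(rbind, lapply(split(d, grp), function(r) {
        if (nrow(r) < min_probes) return(NULL)
        data.frame(chrom = r$chrom[1], start = min(r$pos) - 1L, end = max(r$pos),
                   n_probes = nrow(r), mean_delta = mean(r$delta),
                   direction = r$direction[1], stringsAsFactors = FALSE)
      }))
    })
    regions <- do.call(rbind, regions)
    if (!is.null(regions)) {
      out <- regions[order(regions$chrom, regions$start), ]
      rownames(out) <- NULL
    }
  }
  attr(out, "caller") <- sprintf("gap-merge (max_gap_bp=%d, min_probes=%d)",
                                 as.integer(max_gap_bp), as.integer(min_probes))
  out
}

#' Per-gene promoter methylation
#'
#' Promoter probes are those annotated TSS1500, TSS200, 5'UTR or 1stExon.
#' For each gene with at least one promoter probe, the per-sample promoter
#' methylation is the median beta across its promoter probes.
#'
#' @param beta Probes x samples beta matrix.
#' @param annotation Probe annotation with gene and promoter_class.
#' @return Numeric matrix, genes x samples.
#' @export
gene_promoter_beta <- function(beta, annotation) {
  .check_beta_matrix(beta)
  .check_annotation(annotation)
  promoter <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  use <- ann$promoter_class %in% promoter & !is.na(ann$gene) & ann$gene != ""
  if (!any(use)) stop("no promoter probes with gene annotation found")
  probe_sets <- split(rownames(beta)[use], ann$gene[use])
  out <- t(vapply(probe_sets, function(p) {
    apply(beta[p, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }, numeric(ncol(beta))))
  out[order(rownames(out)), , drop = FALSE]
}

#' Frequently methylated genes
#'
#' Genes likely methylated in normal tissue are removed first: a gene is
#' excluded when more than `normal_fraction` of normal samples have
#' promoter beta >= `normal_beta`, or when its median beta across normals
#' is >= `normal_beta`. Remaining genes are called methylated per tumor at
#' promoter beta >= `call_beta`, and a gene is reported when its call
#' frequency across tumors is strictly greater than `freq_cutoff`.
#'
#' @param tumors Genes x tumor-samples promoter methylation matrix.
#' @param normals Genes x normal-samples matrix, or NULL to skip the normal
#'   filter (with a warning).
#' @param normal_beta Normal-contamination beta threshold (default 0.2).
#' @param normal_fraction Fraction of normals allowed above it (default 0.5).
#' @param call_beta Per-tumor methylation call threshold (default 0.3).
#' @param freq_cutoff Strict tumor-frequency cutoff (default 0.10).
#' @return data.frame with gene, n_methylated, frequency, sorted by
#'   decreasing frequency; the post-normal-filter gene universe is attached
#'   as attribute `filtered_universe`.
#' @export
frequently_methylated_genes <- function(tumors, normals = NULL,
                                        normal_beta = 0.2, normal_fraction = 0.5,
                                        call_beta = 0.3, freq_cutoff = 0.10) {
  genes <- rownames(tumors)
  if (!is.null(normals)) {
    shared <- intersect(genes, rownames(normals))
    if (!setequal(shared, genes)) {
      stop("tumor and normal matrices must share the gene universe")
    }
    nm <- normals[genes, , drop = FALSE]
    frac_high <- rowMeans(nm >= normal_beta, na.rm = TRUE)
    med <- apply(nm, 1, stats::median, na.rm = TRUE)
    genes <- genes[!(frac_high > normal_fraction | med >= normal_beta)]
  } else {
    warning("no normal samples supplied; normal-contamination filter skipped")
  }
  tm <- tumors[genes, , drop = FALSE]
  calls <- tm >= call_beta
  freq <- rowMeans(calls, na.rm = TRUE)
  keep <- freq > freq_cutoff
  out <- data.frame(gene = genes[keep],
                    n_methylated = rowSums(calls, na.rm = TRUE)[keep],
                    frequency = freq[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), ]
  rownames(out) <- NULL
  attr(out, "filtered_universe") <- genes
  out
}

#' Genomic-context enrichment of a probe subset
#'
#' For each annotation category (every promoter class, every CpG-island
#' relation, enhancer and DNase flags), compares the category fraction in a
#' probe subset against the remainder of the universe with a two-sided
#' Fisher exact test on the 2x2 of (in subset) x (in category), BH-adjusted
#' across categories.
#'
#' @param probe_subset Probe ids; must be a subset of `universe`.
#' @param universe Probe-id universe.
#' @param annotation Probe annotation.
#' @return data.frame with category, subset_fraction, universe_fraction,
#'   p_value, fdr.
#' @export
genomic_context_enrichment <- function(probe_subset, universe, annotation) {
  .check_annotation(annotation)
  if (!all(probe_subset %in% universe)) stop("probe_subset must be within universe")
  ann <- annotation[match(universe, annotation$probe_id), ]
  if (anyNA(ann$probe_id)) stop("universe probes missing from annotation")
  in_sub <- universe %in% probe_subset

  cats <- list()
  for (lev in sort(unique(ann$promoter_class))) {
    cats[[paste0("promoter:", lev)]] <- ann$promoter_class == lev
  }
  for (lev in sort(unique(ann$cgi_relation))) {
    cats[[paste0("cgi:", lev)]] <- ann$cgi_relation == lev
  }
  cats[["enhancer"]] <- ann$enhancer_flag
  cats[["dnase"]] <- ann$dnase_flag

  rows <- lapply(names(cats), function(nm) {
    in_cat <- cats[[nm]]
    tab <- matrix(c(sum(in_sub & in_cat), sum(in_sub & !in_cat),
                    sum(!in_sub & in_cat), sum(!in_sub & !in_cat)),
                  2, 2, byrow = TRUE)
    data.frame(category = nm,
               subset_fraction = mean(in_cat[in_sub]),
               universe_fraction = mean(in_cat),
               p_value = fisher_exact(tab, "two_sided")$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Methylation-based tumor-infiltrating lymphocyte (MeTIL-style) score
#'
#' Computes the first principal component of the z-scored beta values of a
#' small CpG set (the published score uses 5 CpGs), sign-oriented so that
#' higher scores correspond to higher inferred lymphocyte infiltration.
#' This is a declared principal-component stand-in for the published score:
#' the CpG set and orientation are fully configurable.
#'
#' @param beta Probes x samples beta matrix.
#' @param cpg_set At least two probe ids, all present in `beta`.
#' @param orientation Numeric vector over `cpg_set` giving the expected sign
#'   of each probe's association with infiltration (default all +1: higher
#'   methylation of the set = higher score). The PC is flipped so that the
#'   loading vector has non-negative inner product with `orientation`.
#' @return Named numeric vector of per-sample scores (all zero for a
#'   variance-free matrix).
#' @export
metil_score <- function(beta, cpg_set, orientation = NULL) {
  .check_beta_matrix(beta)
  if (length(cpg_set) < 2L) stop("cpg_set must contain at least 2 probes")
  if (!all(cpg_set %in% rownames(beta))) stop("cpg_set probes missing from beta")
  if (is.null(orientation)) orientation <- rep(1, length(cpg_set))
  if (length(orientation) != length(cpg_set)) {
    stop("orientation must match cpg_set length")
  }
  x <- beta[cpg_set, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  if (all(z == 0)) {
    return(stats::setNames(rep(0, ncol(beta)), colnames(beta)))
  }
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  flip <- if (sum(load1 * orientation) < 0) -1 else 1
  stats::setNames(flip * pc$x[, 1], colnames(beta))
}
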