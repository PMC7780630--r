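#' End-to-end pipeline configuration
#'
#' Bundles the simulator conditions and every analysis-stage parameter with
#' the study defaults: 500 consensus runs at 80%/80% resampling with k = 2,
#' the 0.4 / 0.2 / FDR < 0.05 hypermethylation rule, the 0.3 promoter-call
#' and strict 10% frequency gene rule, the 50 Mb load convention, the 0.2
#' exposure cutoff, and NMF rank 3.
#'
#' @param sim A [sim_config()]; its seed is re-derived from `seed`.
#' @param stages Character subset of
#'   `c("methylome", "mutations", "survival")` to run.
#' @param variable_fraction Top-variable-probe fraction (default 0.01).
#' @param consensus_runs,k Consensus protocol (default 500 runs, k = 2).
#' @param hyper_mean,hypo_mean,fdr_cutoff Hypermethylation rule thresholds.
#' @param call_beta,freq_cutoff Promoter-gene methylation rule.
#' @param target_mb Exome capture size for load (default 50).
#' @param exposure_cutoff Signature exposure cutoff (default 0.2).
#' @param nmf_rank,nmf_restarts NMF clustering settings (default 3, 30).
#' @param seed Global seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("methylome", "mutations", "survival"),
                            variable_fraction = 0.01,
                            consensus_runs = 500L, k = 2L,
                            hyper_mean = 0.4, hypo_mean = 0.2,
                            fdr_cutoff = 0.05,
                            call_beta = 0.3, freq_cutoff = 0.10,
                            target_mb = 50, exposure_cutoff = 0.2,
                            nmf_rank = 3L, nmf_restarts = 30L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, stages = stages,
                 variable_fraction = variable_fraction,
                 consensus_runs = as.integer(consensus_runs), k = as.integer(k),
                 hyper_mean = hyper_mean, hypo_mean = hypo_mean,
                 fdr_cutoff = fdr_cutoff, call_beta = call_beta,
                 freq_cutoff = freq_cutoff, target_mb = target_mb,
                 exposure_cutoff = exposure_cutoff,
                 nmf_rank = as.integer(nmf_rank),
                 nmf_restarts = as.integer(nmf_restarts),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the integrated synthetic-cohort analysis pipeline
#'
#' Simulates a cohort under `config$sim`, then executes the enabled stages
#' in dependency order: probe QC and top-variable selection, consensus
#' epi-clustering, DMP testing and the hypermethylation signature rule,
#' promoter-gene methylation calling (methylome stage); mutation parsing,
#' load, gene frequencies, 96-channel catalog, exposure fitting and NMF
#' clustering (mutations stage); Kaplan-Meier/log-rank and univariate Cox
#' on the recovered epi-clusters (survival stage). Every stochastic stage
#' draws from a substream of the global seed, so reruns with an identical
#' config are identical; the manifest records the config hash, per-stage
#' timings, accumulated warnings, and recovery metrics against the planted
#' truth (cluster ARI, planted-probe recall).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_manifest` list with `config_hash`, `metrics`,
#'   `results`, `warnings` and `timings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character()
  note <- function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  timings <- c()
  results <- list()
  metrics <- list()

  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(expr, warning = note)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  sim <- tick("simulate_beta", simulate_beta(config$sim))
  truth <- sim$truth
  tumor_ids <- sim$sample_info$sample_id[sim$sample_info$type == "tumor"]

  if ("methylome" %in% config$stages) {
    tumors <- sim$beta[, tumor_ids, drop = FALSE]
    filtered <- tick("filter", filter_probes(tumors, sim$annotation))
    top <- tick("variable", select_variable_probes(filtered,
                                                   config$variable_fraction))
    cparams <- consensus_params(
      n_runs = config$consensus_runs, k = config$k,
      base_distance = "euclidean", base_linkage = "ward_d",
      seed = substream_seed(config$seed, "consensus"))
    cons <- tick("consensus", consensus_cluster(filtered[top, , drop = FALSE],
                                                cparams))
    dmps <- tick("dmps", call_dmps(filtered, cons$labels,
                                   fdr_cutoff = config$fdr_cutoff))
    sig <- derive_hyper_signature(dmps, config$hyper_mean, config$hypo_mean,
                                  config$fdr_cutoff)
    hyper <- if (length(sig$hyper_in_g1) >= length(sig$hyper_in_g2)) {
      sig$hyper_in_g1
    } else sig$hyper_in_g2
    gm <- tick("gene_beta", gene_promoter_beta(sim$beta, sim$annotation))
    normals <- sim$sample_info$sample_id[sim$sample_info$type == "normal"]
    freq_genes <- tick("freq_genes", frequently_methylated_genes(
      gm[, tumor_ids, drop = FALSE],
      if (length(normals)) gm[, normals, drop = FALSE] else NULL,
      call_beta = config$call_beta, freq_cutoff = config$freq_cutoff))
    planted_kept <- intersect(truth$planted_probes, rownames(filtered))
    metrics$epi_cluster_ari <- mclust::adjustedRandIndex(
      cons$labels[tumor_ids], truth$cluster[tumor_ids])
    metrics$planted_probe_recall <-
      if (length(truth$planted_probes)) {
        length(intersect(hyper, truth$planted_probes)) /
          length(truth$planted_probes)
      } else NA_real_
    metrics$hyper_probe_count <- length(hyper)
    results$consensus <- cons
    results$dmps <- dmps
    results$hyper_signature <- sig
    results$frequent_genes <- freq_genes
    results$planted_kept <- planted_kept
  }

  if ("mutations" %in% config$stages) {
    basis <- synthetic_signature_basis(
      n_signatures = length(config$sim$signature_mix[[1]]))
    muts <- tick("simulate_mutations",
                 simulate_mutations(config$sim, basis, truth))
    parsed <- parse_mutations(muts$records, muts$sample_universe)
    load <- mutational_load(parsed$records, parsed$sample_universe,
                            config$target_mb)
    mat <- mutation_matrix(parsed$records, parsed$sample_universe,
                           genes = names(config$sim$driver_spec))
    catalog <- tick("catalog", build_catalog(parsed$records,
                                             parsed$sample_universe))
    fit <- tick("exposures", fit_exposures(catalog, basis,
                                           cutoff = config$exposure_cutoff))
    nmf <- tick("nmf", nmf_cluster(
      fit$exposures, rank = config$nmf_rank,
      n_restarts = config$nmf_restarts,
      seed = substream_seed(config$seed, "nmf")))
    metrics$mean_load <- unname(load$summary["mean"])
    metrics$median_load <- unname(load$summary["median"])
    # exposure recovery is only identifiable at adequate catalog depth;
    # shallow catalogs are reported through the mean error instead
    ok <- !(rownames(fit$exposures) %in% fit$skipped)
    errs <- abs(fit$exposures[ok, , drop = FALSE] -
                  muts$truth$exposures[rownames(fit$exposures)[ok], , drop = FALSE])
    metrics$exposure_mean_abs_error <- mean(errs)
    deep <- rowSums(catalog)[ok] >= 500
    metrics$exposure_max_error_deep <-
      if (any(deep)) max(errs[deep, , drop = FALSE]) else NA_real_
    results$class_distribution <- parsed$class_distribution
    results$load <- load
    results$mutation_matrix <- mat
    results$gene_frequency <- gene_frequency(mat)
    results$exposures <- fit
    results$nmf <- nmf
    results$contributors <- extract_contributors(nmf)
  }

  if ("survival" %in% config$stages) {
    clin <- tick("clinical", simulate_clinical(config$sim, truth))
    grp <- factor(truth$cluster[clin$sample_id], levels = c(2, 1),
                  labels = c("low", "high"))
    km <- km_logrank(clin, grp, "os")
    cox <- cox_univariate(clin, grp, "os")
    metrics$logrank_p <- km$p_value
    metrics$cox_hr <- cox$hr
    results$clinical <- clin
    results$km <- km
    results$cox <- cox
  }

  structure(list(config_hash = .config_hash(config), metrics = metrics,
                 results = results, warnings = warnings, timings = timings),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline manifest", x$config_hash, "\n")
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-24s %s\n", nm, format(x$metrics[[nm]], digits = 4)))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Published reference counts for a 30-tumor UTUC whole-exome cohort
#'
#' Headline summary statistics reported for the 30-sample upper-tract
#' urothelial carcinoma whole-exome cohort this pipeline was designed
#' around, used by [validate_against_supplement()] for side-by-side
#' display. These are external published values, not computed by this
#' package.
#'
#' @return Named list of reference quantities.
#' @export
utuc_reference_counts <- function() {
  list(total_mutations = 4239, missense = 2569, silent = 1081, indels = 272,
       load_mean = 2.9, load_median = 1.5,
       FGFR3_frequency_pct = 50, KDM6A_frequency_pct = 27,
       ZFP36L1_frequency_pct = 20, ZFP36_family_frequency_pct = 26.7,
       ZFP36L1_record_count = 8, n_samples = 30)
}

#' Validate a supplementary mutation table against published counts
#'
#' Recomputes, from any Table-of-somatic-mutations-formatted MAF, the total
#' and per-class mutation counts, the load summaries under the sum / 50 Mb
#' rule, the key gene frequencies and the ZFP36-family frequency, and
#' prints them side by side with reference values. Informational only: the
#' report never fails, and with `reference = NULL` the comparison column
#' is N/A.
#'
#' @param x MAF path or data.frame.
#' @param sample_universe Optional full sample list (default: observed).
#' @param reference Named list of reference values as produced by
#'   [utuc_reference_counts()], or NULL.
#' @param target_mb Capture size for load (default 50).
#' @param verbose Print the side-by-side table (default TRUE).
#' @return data.frame with metric, computed, reference (invisibly; also
#'   printed when `verbose`).
#' @export
validate_against_supplement <- function(x, sample_universe = NULL,
                                        reference = utuc_reference_counts(),
                                        target_mb = 50, verbose = TRUE) {
  parsed <- parse_mutations(x, sample_universe)
  dist <- parsed$class_distribution
  load <- mutational_load(parsed$records, parsed$sample_universe, target_mb)
  mat <- mutation_matrix(parsed$records, parsed$sample_universe)
  freq <- gene_frequency(mat, families = list(
    ZFP36_family = c("ZFP36", "ZFP36L1", "ZFP36L2")))
  pct <- function(g) {
    i <- match(g, freq$gene)
    if (is.na(i)) NA_real_ else round(100 * freq$frequency[i], 1)
  }
  computed <- list(
    total_mutations = attr(dist, "total"),
    missense = dist$n[dist$class == "missense"],
    silent = dist$n[dist$class == "silent"],
    indels = attr(dist, "indel"),
    load_mean = round(unname(load$summary["mean"]), 1),
    load_median = round(unname(load$summary["median"]), 1),
    FGFR3_frequency_pct = pct("FGFR3"),
    KDM6A_frequency_pct = pct("KDM6A"),
    ZFP36L1_frequency_pct = pct("ZFP36L1"),
    ZFP36_family_frequency_pct = pct("ZFP36_family"),
    ZFP36L1_record_count = sum(parsed$records$gene == "ZFP36L1"),
    n_samples = length(parsed$sample_universe))
  ref <- vapply(names(computed), function(nm) {
    if (is.null(reference) || is.null(reference[[nm]])) NA_real_
    else as.numeric(reference[[nm]])
  }, numeric(1))
  out <- data.frame(metric = names(computed),
                    computed = as.numeric(unlist(computed)),
                    reference = ref, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (verbose) print(out)
  invisible(out)
}
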