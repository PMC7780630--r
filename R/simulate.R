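#' Synthetic multi-omics cohort configuration
#'
#' Encodes the study conditions the simulator emulates: a tumor cohort with
#' two latent methylome clusters and a planted hypermethylated probe block,
#' driver-gene mutation probabilities that differ between clusters,
#' per-sample mutation catalogs drawn from trinucleotide-signature mixtures,
#' and cluster-dependent survival hazards. Defaults describe a 60-tumor
#' cohort split 60/40 with a 200-probe block at mean beta 0.65 in cluster 1
#' versus 0.10 elsewhere, a background exome load averaging 145 mutations
#' (2.9 per Mb under the 50 Mb capture convention), and a true
#' between-cluster hazard ratio of 6.57.
#'
#' @param n_tumors,n_normals,n_probes Cohort dimensions.
#' @param cluster_proportions Fractions summing to 1 (within 1e-9); one per
#'   latent cluster.
#' @param planted_hyper_block Number of autosomal probes hypermethylated in
#'   cluster 1 only.
#' @param beta_high_params,beta_low_params `c(mean, precision)` of the
#'   bounded Beta noise for the high- and low-methylation states; the Beta
#'   shapes are `mean * precision` and `(1 - mean) * precision`.
#' @param na_rate Fraction of beta entries set missing.
#' @param sex_chrom_fraction Fraction of probes annotated to chrX/chrY.
#' @param driver_spec Named list: per driver gene a vector of per-cluster
#'   mutation probabilities.
#' @param background_load `c(mu, size)` of the negative-binomial per-sample
#'   background mutation count.
#' @param class_mix Named probability vector over variant classes.
#' @param signature_mix List of per-cluster exposure vectors over the
#'   signature basis columns (each sums to 1).
#' @param hazard_by_cluster Positive hazard multipliers, one per cluster.
#' @param baseline_hazard Baseline event hazard per month.
#' @param censoring_rate Expected censored fraction on the baseline arm
#'   (independent exponential censoring); 1 means administratively censor
#'   everything.
#' @param mi_prob_by_cluster Per-cluster probability of muscle-invasive
#'   (MI) status.
#' @param seed Global integer seed; each simulate_* stage derives its own
#'   substream via [substream_seed()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tumors = 60L, n_normals = 8L, n_probes = 5000L,
                       cluster_proportions = c(0.6, 0.4),
                       planted_hyper_block = 200L,
                       beta_high_params = c(mean = 0.65, precision = 15),
                       beta_low_params = c(mean = 0.10, precision = 15),
                       na_rate = 0, sex_chrom_fraction = 0.02,
                       driver_spec = list(
                         FGFR3 = c(0.28, 0.90), ARID1A = c(0.50, 0.00),
                         KDM6A = c(0.27, 0.27), ZFP36L1 = c(0.20, 0.20),
                         KMT2C = c(0.30, 0.30), STAG2 = c(0.23, 0.23),
                         TP53 = c(0.17, 0.17)),
                       background_load = c(mu = 145, size = 0.7),
                       class_mix = c(missense = 0.606, silent = 0.255,
                                     nonsense = 0.040, splice = 0.020,
                                     frameshift_ins = 0.020,
                                     frameshift_del = 0.025,
                                     inframe_indel = 0.019, other = 0.015),
                       signature_mix = list(c(0.6, 0.4, 0, 0, 0),
                                            c(0, 0, 0.7, 0.3, 0)),
                       hazard_by_cluster = c(6.57, 1),
                       baseline_hazard = 0.02,
                       censoring_rate = 0.2,
                       mi_prob_by_cluster = c(16 / 23, 1 / 12),
                       seed = 1L) {
  k <- length(cluster_proportions)
  if (abs(sum(cluster_proportions) - 1) > 1e-9) {
    stop("cluster_proportions must sum to 1 within 1e-9")
  }
  .check_prob(cluster_proportions, "cluster_proportions")
  .check_prob(na_rate, "na_rate")
  .check_prob(sex_chrom_fraction, "sex_chrom_fraction")
  .check_prob(censoring_rate, "censoring_rate")
  .check_prob(unlist(driver_spec), "driver_spec")
  .check_prob(mi_prob_by_cluster, "mi_prob_by_cluster")
  if (planted_hyper_block > n_probes) stop("planted_hyper_block must be <= n_probes")
  if (any(lengths(driver_spec) != k)) {
    stop("each driver_spec entry needs one probability per cluster")
  }
  if (length(signature_mix) != k) stop("signature_mix needs one vector per cluster")
  if (length(hazard_by_cluster) != k || any(hazard_by_cluster <= 0)) {
    stop("hazard_by_cluster must be positive, one per cluster")
  }
  for (p in list(beta_high_params, beta_low_params)) {
    if (length(p) != 2 || p[1] <= 0 || p[1] >= 1 || p[2] <= 0) {
      stop("beta state params must be c(mean in (0,1), precision > 0)")
    }
  }
  structure(list(
    n_tumors = as.integer(n_tumors), n_normals = as.integer(n_normals),
    n_probes = as.integer(n_probes), cluster_proportions = cluster_proportions,
    planted_hyper_block = as.integer(planted_hyper_block),
    beta_high_params = beta_high_params, beta_low_params = beta_low_params,
    na_rate = na_rate, sex_chrom_fraction = sex_chrom_fraction,
    driver_spec = driver_spec, background_load = background_load,
    class_mix = class_mix / sum(class_mix), signature_mix = signature_mix,
    hazard_by_cluster = hazard_by_cluster, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, mi_prob_by_cluster = mi_prob_by_cluster,
    seed = as.integer(seed)), class = "sim_config")
}

.rbeta_state <- function(n, params) {
  stats::rbeta(n, shape1 = params[1] * params[2],
               shape2 = (1 - params[1]) * params[2])
}

# deterministic largest-remainder apportioning of n into proportions
.apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Simulate a methylation beta matrix with a planted hypermethylated block
#'
#' Background probes get a per-probe bimodal baseline state (high or low
#' methylation) shared by all tumors and normals, so they are variable
#' across probes but not differential. Planted block probes are drawn from
#' the high state in cluster-1 tumors and from the low state in all other
#' tumors and in normals. Probes annotated to sex chromosomes and missing
#' entries are injected at the configured rates so the QC filters have work
#' to do. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `beta` (probes x samples, tumors then normals),
#'   `annotation`, `sample_info` (sample_id, type) and `truth` (cluster
#'   labels per tumor, planted probe ids, config echo).
#' @export
simulate_beta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(substream_seed(config$seed, "beta"), {
    np <- config$n_probes
    nt <- config$n_tumors
    nn <- config$n_normals
    k <- length(config$cluster_proportions)

    probe_ids <- sprintf("cg%07d", seq_len(np))
    n_sex <- round(config$sex_chrom_fraction * np)
    sex_idx <- if (n_sex > 0) sample.int(np, n_sex) else integer()
    chrom <- paste0("chr", sample(1:22, np, replace = TRUE))
    chrom[sex_idx] <- sample(c("chrX", "chrY"), length(sex_idx), replace = TRUE)
    pos <- sample.int(2e8L, np, replace = TRUE)
    n_genes <- max(1L, np %/% 10L)
    gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
    gene <- sample(gene_pool, np, replace = TRUE)
    gene[stats::runif(np) < 0.2] <- ""  # intergenic probes
    promoter_class <- sample(
      c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR", "IGR"),
      np, replace = TRUE, prob = c(0.10, 0.08, 0.07, 0.05, 0.35, 0.05, 0.30))
    cgi_relation <- sample(c("island", "shore", "shelf", "open_sea"),
                           np, replace = TRUE, prob = c(0.3, 0.2, 0.1, 0.4))
    annotation <- data.frame(
      probe_id = probe_ids, chrom = chrom, pos = pos, gene = gene,
      promoter_class = promoter_class, cgi_relation = cgi_relation,
      enhancer_flag = stats::runif(np) < 0.05,
      dnase_flag = stats::runif(np) < 0.30, stringsAsFactors = FALSE)

    sizes <- .apportion(nt, config$cluster_proportions)
    cluster <- rep(seq_len(k), times = sizes)
    tumor_ids <- sprintf("T%03d", seq_len(nt))
    normal_ids <- if (nn > 0) sprintf("N%03d", seq_len(nn)) else character()

    planted <- if (config$planted_hyper_block > 0) {
      autosomal <- setdiff(seq_len(np), sex_idx)
      sort(sample(autosomal, config$planted_hyper_block))
    } else integer()

    # bimodal background baseline per probe, shared by every sample
    hi <- config$beta_high_params
    lo <- config$beta_low_params
    baseline_high <- stats::runif(np) < 0.35
    n_samp <- nt + nn
    beta <- matrix(NA_real_, np, n_samp,
                   dimnames = list(probe_ids, c(tumor_ids, normal_ids)))
    bg_hi <- which(baseline_high)
    bg_lo <- which(!baseline_high)
    beta[bg_hi, ] <- .rbeta_state(length(bg_hi) * n_samp, hi)
    beta[bg_lo, ] <- .rbeta_state(length(bg_lo) * n_samp, lo)
    if (length(planted)) {
      c1 <- which(cluster == 1L)
      beta[planted, ] <- .rbeta_state(length(planted) * n_samp, lo)
      beta[planted, c1] <- .rbeta_state(length(planted) * length(c1), hi)
    }
    if (config$na_rate > 0) {
      beta[stats::runif(length(beta)) < config$na_rate] <- NA_real_
    }

    truth <- list(cluster = stats::setNames(cluster, tumor_ids),
                  planted_probes = probe_ids[planted],
                  config = config)
    list(beta = beta, annotation = annotation,
         sample_info = data.frame(
           sample_id = c(tumor_ids, normal_ids),
           type = rep(c("tumor", "normal"), c(nt, nn)),
           stringsAsFactors = FALSE),
         truth = truth)
  })
}

.decode_channel <- function(channel) {
  # "A[C>T]G" -> ref, alt, 3-mer context
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  ctx <- paste0(substr(channel, 1, 1), ref, substr(channel, 7, 7))
  list(ref = ref, alt = alt, context = ctx)
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), ""))
}

#' Simulate a MAF-like somatic mutation table
#'
#' Per-sample background counts follow the configured negative binomial;
#' every single-base substitution is assigned a 96-channel trinucleotide
#' context drawn from the sample's cluster signature mixture over `basis`
#' (contexts are i.i.d. across mutations; genomic position carries no
#' signal). Half the SNV records are emitted on the purine strand to
#' exercise the catalog's strand folding. Driver genes are additionally
#' mutated per the per-cluster probabilities of `config$driver_spec`.
#'
#' @param config A [sim_config()].
#' @param basis 96 x S column-stochastic signature basis.
#' @param truth Truth object from [simulate_beta()] supplying cluster
#'   labels; if NULL labels are re-derived from the config proportions.
#' @return List with `records` (MAF-like data.frame), `sample_universe`
#'   and `truth` extended with `exposures` (true per-sample mixture) and
#'   `driver_matrix`.
#' @export
simulate_mutations <- function(config, basis, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .check_basis(basis)
  if (any(vapply(config$signature_mix, length, 1L) != ncol(basis))) {
    stop("signature_mix vectors must have one weight per basis column")
  }
  withr::with_seed(substream_seed(config$seed, "mutations"), {
    nt <- config$n_tumors
    tumor_ids <- sprintf("T%03d", seq_len(nt))
    cluster <- if (!is.null(truth)) truth$cluster[tumor_ids] else {
      stats::setNames(rep(seq_along(config$cluster_proportions),
                          times = .apportion(nt, config$cluster_proportions)),
                      tumor_ids)
    }
    channels <- sbs96_channels()
    snv_classes <- c("missense", "silent", "nonsense")
    cm <- config$class_mix
    recs <- vector("list", nt)
    for (i in seq_len(nt)) {
      n_mut <- stats::rnbinom(1, mu = config$background_load["mu"],
                              size = config$background_load["size"])
      cls <- if (n_mut > 0) {
        sample(names(cm), n_mut, replace = TRUE, prob = cm)
      } else character()
      mix <- config$signature_mix[[cluster[i]]]
      chan_prob <- as.vector(basis %*% mix)
      is_snv <- cls %in% snv_classes
      ref <- alt <- ctx <- character(n_mut)
      if (any(is_snv)) {
        ch <- sample(channels, sum(is_snv), replace = TRUE, prob = chan_prob)
        dec <- .decode_channel(ch)
        flip <- stats::runif(sum(is_snv)) < 0.5
        ref[is_snv] <- ifelse(flip, chartr("ACGT", "TGCA", dec$ref), dec$ref)
        alt[is_snv] <- ifelse(flip, chartr("ACGT", "TGCA", dec$alt), dec$alt)
        ctx[is_snv] <- ifelse(flip, .revcomp(dec$context), dec$context)
      }
      if (any(!is_snv)) {
        ref[!is_snv] <- sample(c("A", "C", "G", "T"), sum(!is_snv), replace = TRUE)
        alt[!is_snv] <- "-"
      }
      drv <- names(config$driver_spec)[
        stats::runif(length(config$driver_spec)) <
          vapply(config$driver_spec, `[`, 0, cluster[i])]
      n_drv <- length(drv)
      drv_ref <- drv_alt <- drv_ctx <- character(n_drv)
      if (n_drv > 0) {
        ch <- sample(channels, n_drv, replace = TRUE, prob = chan_prob)
        dec <- .decode_channel(ch)
        drv_ref <- dec$ref; drv_alt <- dec$alt; drv_ctx <- dec$context
      }
      n_all <- n_mut + n_drv
      if (n_all == 0) { recs[[i]] <- NULL; next }
      recs[[i]] <- data.frame(
        sample_id = tumor_ids[i],
        gene = c(sample(sprintf("BG%04d", 1:400), n_mut, replace = TRUE), drv),
        chrom = paste0("chr", sample(1:22, n_all, replace = TRUE)),
        pos = sample.int(2e8L, n_all, replace = TRUE),
        ref = c(ref, drv_ref), alt = c(alt, drv_alt),
        variant_class = c(cls, rep("missense", n_drv)),
        context = c(ctx, drv_ctx), stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    exposures <- do.call(rbind, config$signature_mix)[cluster, , drop = FALSE]
    dimnames(exposures) <- list(tumor_ids, colnames(basis))
    driver_genes <- names(config$driver_spec)
    driver_matrix <- matrix(FALSE, length(driver_genes), length(tumor_ids),
                            dimnames = list(driver_genes, tumor_ids))
    for (s in tumor_ids) {
      g <- unique(records$gene[records$sample_id == s])
      driver_matrix[, s] <- driver_genes %in% g
    }
    truth_out <- c(if (is.null(truth)) list(cluster = cluster) else truth,
                   list(exposures = exposures, driver_matrix = driver_matrix))
    list(records = records, sample_universe = tumor_ids, truth = truth_out)
  })
}

#' Simulate clinical and survival data with cluster-dependent hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_by_cluster[cluster]`; censoring is an
#' independent exponential whose rate is chosen so the expected censored
#' fraction on the baseline-hazard arm equals `censoring_rate`.
#' Progression-free times are a scaled copy of the overall-survival times
#' (the generator makes no attempt at distinct PFS biology). MI status is
#' drawn per cluster from `mi_prob_by_cluster`. A `censoring_rate` of 1
#' censors everything and tags the result degenerate, since no survival
#' contrast is estimable.
#'
#' @param config A [sim_config()].
#' @param truth Truth object carrying per-tumor cluster labels.
#' @return data.frame with sample_id, cluster, mi_status, os_time,
#'   os_event, pfs_time, pfs_event, age, sex, stage, grade; attribute
#'   `degenerate` flags the all-censored case.
#' @export
simulate_clinical <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cluster <- truth$cluster
  nt <- length(cluster)
  withr::with_seed(substream_seed(config$seed, "clinical"), {
    h <- config$baseline_hazard * config$hazard_by_cluster[cluster]
    t_event <- stats::rexp(nt, rate = h)
    degenerate <- FALSE
    if (config$censoring_rate >= 1) {
      os_time <- t_event
      os_event <- rep(FALSE, nt)
      degenerate <- TRUE
      warning("censoring_rate = 1: all observations censored; survival contrasts are degenerate")
    } else if (config$censoring_rate > 0) {
      cr <- config$censoring_rate
      c_rate <- config$baseline_hazard * cr / (1 - cr)
      t_cens <- stats::rexp(nt, rate = c_rate)
      os_time <- pmin(t_event, t_cens)
      os_event <- t_event <= t_cens
    } else {
      os_time <- t_event
      os_event <- rep(TRUE, nt)
    }
    pfs_scale <- stats::runif(nt, 0.5, 1)
    out <- data.frame(
      sample_id = names(cluster), cluster = as.integer(cluster),
      mi_status = ifelse(stats::runif(nt) < config$mi_prob_by_cluster[cluster],
                         "MI", "NMI"),
      os_time = os_time, os_event = os_event,
      pfs_time = os_time * pfs_scale, pfs_event = os_event,
      age = round(stats::rnorm(nt, 70, 9)),
      sex = sample(c("M", "F"), nt, replace = TRUE, prob = c(0.7, 0.3)),
      stage = sample(c("pTa", "pT1", "pT2", "pT3"), nt, replace = TRUE),
      grade = sample(c("low", "high"), nt, replace = TRUE),
      stringsAsFactors = FALSE)
    attr(out, "degenerate") <- degenerate
    out
  })
}

#' Simulate an external validation cohort on a reduced probe universe
#'
#' Emulates transferring a hypermethylation signature onto a cohort
#' profiled on a smaller array: only `overlap_fraction` of the signature
#' probes exist in the external universe (plus background probes), but the
#' overlapping probes carry the same two-state structure (high in cluster
#' 1, low elsewhere). Zero overlap is an error since transfer is then
#' impossible.
#'
#' @param config A [sim_config()] (supplies sample counts, states, seed).
#' @param signature_probes Non-empty probe-id vector to overlap with.
#' @param overlap_fraction Fraction of `signature_probes` present in the
#'   external universe; default 0.27, the order of overlap seen when an
#'   EPIC-derived signature is intersected with a 450k array.
#' @param n_background Background (non-signature) probes in the external
#'   universe.
#' @return List with `beta` and `truth` (external cluster labels).
#' @export
simulate_external_cohort <- function(config, signature_probes,
                                     overlap_fraction = 0.27,
                                     n_background = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(signature_probes)) stop("signature_probes must be non-empty")
  n_keep <- floor(overlap_fraction * length(signature_probes))
  if (overlap_fraction <= 0 || n_keep == 0) {
    stop("zero overlap with the external probe universe; transfer impossible")
  }
  withr::with_seed(substream_seed(config$seed, "external"), {
    kept <- sort(sample(signature_probes, n_keep))
    bg_ids <- sprintf("ext%06d", seq_len(n_background))
    nt <- config$n_tumors
    sizes <- .apportion(nt, config$cluster_proportions)
    cluster <- rep(seq_along(sizes), times = sizes)
    ids <- sprintf("E%03d", seq_len(nt))
    hi <- config$beta_high_params
    lo <- config$beta_low_params
    np <- n_keep + n_background
    beta <- matrix(NA_real_, np, nt, dimnames = list(c(kept, bg_ids), ids))
    baseline_high <- stats::runif(n_background) < 0.35
    bg <- n_keep + seq_len(n_background)
    beta[bg[baseline_high], ] <- .rbeta_state(sum(baseline_high) * nt, hi)
    beta[bg[!baseline_high], ] <- .rbeta_state(sum(!baseline_high) * nt, lo)
    c1 <- which(cluster == 1L)
    beta[seq_len(n_keep), ] <- .rbeta_state(n_keep * nt, lo)
    beta[seq_len(n_keep), c1] <- .rbeta_state(n_keep * length(c1), hi)
    list(beta = beta,
         truth = list(cluster = stats::setNames(cluster, ids),
                      overlap_probes = kept))
  })
}
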