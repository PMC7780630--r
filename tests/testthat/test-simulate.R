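test_that("configuration invariants are enforced", {
  expect_error(sim_config(cluster_proportions = c(0.6, 0.5)), "sum to 1")
  expect_error(sim_config(na_rate = 1.2), "na_rate")
  expect_error(sim_config(planted_hyper_block = 10, n_probes = 5), "<= n_probes")
  expect_error(sim_config(hazard_by_cluster = c(1, -1)), "positive")
  expect_error(sim_config(driver_spec = list(FGFR3 = c(0.5, 1.5))), "driver_spec")
})

test_that("the generator honours the seed contract and the beta value bounds", {
  cfg <- sim_config(n_tumors = 20, n_probes = 500, seed = 4)
  a <- simulate_beta(cfg)
  b <- simulate_beta(cfg)
  expect_identical(a, b)

  cfg2 <- sim_config(n_tumors = 20, n_probes = 500, seed = 5)
  expect_false(identical(a$beta, simulate_beta(cfg2)$beta))

  vals <- a$beta[!is.na(a$beta)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(a$truth$planted_probes %in% a$annotation$probe_id))
  expect_length(a$truth$cluster, 20)
})

test_that("missingness and sex-probe fractions land near their configured rates", {
  cfg <- sim_config(n_tumors = 12, n_normals = 0, n_probes = 10000,
                    na_rate = 0.02, sex_chrom_fraction = 0.05, seed = 2)
  sim <- simulate_beta(cfg)
  na_frac <- mean(is.na(sim$beta))
  expect_gt(na_frac, 0.02 * 0.8)
  expect_lt(na_frac, 0.02 * 1.2)
  sex_frac <- mean(sub("^chr", "", sim$annotation$chrom) %in% c("X", "Y"))
  expect_equal(sex_frac, 0.05, tolerance = 0.01)
})

test_that("a no-signal configuration yields no reproducible split", {
  cfg <- sim_config(n_tumors = 24, n_probes = 600, planted_hyper_block = 0,
                    sex_chrom_fraction = 0, seed = 8)
  sim <- simulate_beta(cfg)
  top <- select_variable_probes(sim$beta[, 1:24], 0.1)
  res <- consensus_cluster(sim$beta[top, 1:24],
                           consensus_params(n_runs = 60, seed = 3,
                                            base_distance = "euclidean",
                                            base_linkage = "ward_d"))
  off <- res$consensus[upper.tri(res$consensus)]
  expect_gt(mean(off), 0.2)  # neither crisp co-clustering ...
  expect_lt(mean(off), 0.8)  # ... nor crisp separation
})

test_that("driver mutations follow the per-cluster probabilities exactly at 0/1", {
  cfg <- sim_config(n_tumors = 20, n_probes = 200, planted_hyper_block = 50,
                    driver_spec = list(FGFR3 = c(1, 0)),
                    signature_mix = list(c(1, 0), c(0, 1)),
                    seed = 6)
  basis <- synthetic_signature_basis(2)
  sim <- simulate_beta(cfg)
  mu <- simulate_mutations(cfg, basis, sim$truth)
  mat <- mutation_matrix(mu$records, mu$sample_universe, genes = "FGFR3")
  in_c1 <- names(sim$truth$cluster)[sim$truth$cluster == 1]
  expect_true(all(mat["FGFR3", in_c1] == 1))
  expect_true(all(mat["FGFR3", setdiff(colnames(mat), in_c1)] == 0))
})

test_that("mutation simulation rejects a non-stochastic basis and matches the load target", {
  cfg <- sim_config(n_tumors = 40, n_probes = 100, planted_hyper_block = 0,
                    seed = 3)
  bad <- synthetic_signature_basis(5) * 2
  expect_error(simulate_mutations(cfg, bad), "sum to 1")

  basis <- synthetic_signature_basis(5)
  mu <- simulate_mutations(cfg, basis)
  load <- mutational_load(mu$records, mu$sample_universe)
  # background mean 145 per exome ~ 2.9 per Mb under the 50 Mb convention
  expect_gt(load$summary[["mean"]], 1.5)
  expect_lt(load$summary[["mean"]], 4.5)
})

test_that("pure-signature cohorts are recovered by the exposure fit", {
  cfg <- sim_config(n_tumors = 6, n_probes = 100, planted_hyper_block = 0,
                    cluster_proportions = c(0.5, 0.5),
                    signature_mix = list(c(1, 0, 0), c(1, 0, 0)),
                    background_load = c(mu = 1000, size = 50),
                    driver_spec = list(FGFR3 = c(0.3, 0.3)),
                    seed = 12)
  basis <- synthetic_signature_basis(3)
  mu <- simulate_mutations(cfg, basis)
  cat96 <- build_catalog(mu$records, mu$sample_universe)
  fit <- fit_exposures(cat96, basis)
  expect_true(all(fit$exposures[, 1] >= 0.95))
  expect_true(all(fit$exposures[, 2:3] == 0))
})

test_that("clinical simulation is null-calibrated and flags the all-censored case", {
  cfg <- sim_config(n_tumors = 120, n_probes = 50, planted_hyper_block = 0,
                    hazard_by_cluster = c(1, 1), censoring_rate = 0.1, seed = 1)
  loghrs <- vapply(1:10, function(r) {
    c2 <- cfg; c2$seed <- as.integer(r * 13)
    truth <- list(cluster = setNames(rep(1:2, 60), sprintf("T%03d", 1:120)))
    clin <- simulate_clinical(c2, truth)
    cox_univariate(clin, factor(clin$cluster), "os")$log_hr
  }, numeric(1))
  expect_lt(abs(mean(loghrs)), 0.15)

  cfg_cens <- sim_config(n_tumors = 10, n_probes = 50,
                         planted_hyper_block = 0, censoring_rate = 1)
  truth <- list(cluster = setNames(rep(1:2, 5), sprintf("T%03d", 1:10)))
  expect_warning(clin <- simulate_clinical(cfg_cens, truth), "degenerate")
  expect_true(attr(clin, "degenerate"))
  expect_true(all(!clin$os_event))
  km <- km_logrank(clin, clin$cluster, "os")
  expect_true(km$degenerate)
})

test_that("external cohorts transfer the signature and zero overlap is an error", {
  cfg <- sim_config(n_tumors = 30, n_probes = 400, planted_hyper_block = 100,
                    seed = 10)
  sim <- simulate_beta(cfg)
  sig <- sim$truth$planted_probes
  expect_error(simulate_external_cohort(cfg, sig, overlap_fraction = 0),
               "transfer impossible")
  expect_error(simulate_external_cohort(cfg, character()), "non-empty")

  ext <- simulate_external_cohort(cfg, sig, overlap_fraction = 1,
                                  n_background = 500)
  res <- transfer_signature(ext$beta, sig, consensus_params(n_runs = 60, seed = 4))
  expect_equal(res$n_intersect, 100)
  expect_gte(mclust::adjustedRandIndex(res$labels, ext$truth$cluster), 0.9)
})

test_that("null cohorts rarely produce significant hyper-probes (empirical FDR control)", {
  hits <- vapply(1:40, function(r) {
    cfg <- sim_config(n_tumors = 20, n_normals = 0, n_probes = 400,
                      planted_hyper_block = 0, sex_chrom_fraction = 0,
                      seed = 1000 + r)
    sim <- simulate_beta(cfg)
    labels <- rep(1:2, 10)  # arbitrary split of an unstructured cohort
    dmps <- call_dmps(sim$beta, labels)
    sig <- derive_hyper_signature(dmps)
    length(sig$hyper_in_g1) + length(sig$hyper_in_g2)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})
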