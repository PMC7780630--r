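test_that("probe filtering removes sex-chromosome and missing-value probes, preserving order", {
  fx <- toy_beta_fixture()
  out <- filter_probes(fx$beta, fx$annotation)
  expect_equal(nrow(out), 7)  # 10 - 2 on chrX - 1 with an NA
  expect_false(any(c("p03", "p05", "p04") %in% rownames(out)))
  expect_equal(rownames(out), setdiff(rownames(fx$beta), c("p03", "p04", "p05")))

  clean <- fx$beta[c("p01", "p02", "p06"), ]
  expect_identical(filter_probes(clean, fx$annotation), clean)
})

test_that("unknown chromosome names are reported as an error", {
  fx <- toy_beta_fixture()
  fx$annotation$chrom[1] <- "chr99"
  expect_error(filter_probes(fx$beta, fx$annotation), "chr99")
})

test_that("detection p-value filtering drops failing probes", {
  fx <- toy_beta_fixture()
  beta <- fx$beta[c("p01", "p02", "p06"), ]
  dp <- matrix(0.01, 3, 3, dimnames = dimnames(beta))
  dp["p02", 2] <- 0.2
  out <- filter_probes(beta, fx$annotation, detection_p = dp)
  expect_equal(rownames(out), c("p01", "p06"))
})

test_that("variable-probe selection matches an exhaustive ranking oracle", {
  set.seed(42)
  beta <- matrix(runif(100 * 8), 100, 8,
                 dimnames = list(sprintf("cg%03d", 1:100), paste0("s", 1:8)))
  got <- select_variable_probes(beta, 0.05)
  v <- apply(beta, 1, var)
  expected <- names(sort(v, decreasing = TRUE))[1:5]
  expect_setequal(got, expected)
  expect_length(got, 5)

  expect_setequal(select_variable_probes(beta, 1.0), rownames(beta))
  expect_error(select_variable_probes(beta, 0), "fraction")
})

test_that("DMP testing flags a planted block and gives constant probes p = 1", {
  set.seed(7)
  n1 <- 10; n2 <- 10
  hi <- matrix(rbeta(50 * n1, 0.65 * 15, 0.35 * 15), 50)
  lo <- matrix(rbeta(50 * n2, 0.10 * 15, 0.90 * 15), 50)
  flat <- matrix(rbeta(150 * (n1 + n2), 3, 7), 150)
  beta <- rbind(cbind(hi, lo), flat)
  dimnames(beta) <- list(sprintf("cg%03d", 1:200), sprintf("s%02d", 1:20))
  labels <- rep(c("C1", "C2"), c(n1, n2))

  dmps <- call_dmps(beta, labels)
  planted <- sprintf("cg%03d", 1:50)
  recall <- mean(dmps$significant[match(planted, dmps$probe_id)])
  expect_gte(recall, 0.95)
  expect_lt(mean(dmps$significant[-(1:50)]), 0.05)

  beta2 <- beta
  beta2[60, ] <- 0.4
  dmps2 <- call_dmps(beta2, labels)
  expect_equal(dmps2$p_value[60], 1)
})

test_that("the hypermethylation rule respects its boundaries and is threshold-monotone", {
  dmps <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    mean_beta_g1 = c(0.39, 0.45, 0.80, 0.50),
    mean_beta_g2 = c(0.05, 0.21, 0.10, 0.15),
    delta = c(0.34, 0.24, 0.70, 0.35),
    p_value = c(1e-5, 1e-5, 1e-5, 0.2),
    fdr = c(1e-4, 1e-4, 1e-4, 0.3),
    stringsAsFactors = FALSE)
  sig <- derive_hyper_signature(dmps)
  expect_equal(sig$hyper_in_g1, "c")  # a fails the 0.4 floor, b the 0.2 cap, d the FDR

  relaxed <- derive_hyper_signature(dmps, hyper_mean = 0.3, fdr_cutoff = 0.5)
  expect_true(all(sig$hyper_in_g1 %in% relaxed$hyper_in_g1))
  expect_true(all(c("a", "d") %in% relaxed$hyper_in_g1))
})

test_that("hyper signature equals the planted block exactly on a strong-effect cohort", {
  cfg <- sim_config(n_tumors = 40, n_probes = 2000, planted_hyper_block = 100,
                    seed = 9)
  sim <- simulate_beta(cfg)
  tumors <- filter_probes(sim$beta[, 1:40], sim$annotation)
  dmps <- call_dmps(tumors, sim$truth$cluster)
  sig <- derive_hyper_signature(dmps)
  expect_setequal(sig$hyper_in_g1, sim$truth$planted_probes)
  expect_length(sig$hyper_in_g2, 0)
})

test_that("gap-merge DMR calling follows the 1 kb / 2-probe rule and never crosses directions", {
  ann <- data.frame(
    probe_id = c("a", "b", "c", "d", "e"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 600L, 5000L, 100L, 500L),
    gene = "", promoter_class = "Body", cgi_relation = "open_sea",
    enhancer_flag = FALSE, dnase_flag = FALSE, stringsAsFactors = FALSE)
  dmps <- data.frame(
    probe_id = c("a", "b", "c", "d", "e"),
    mean_beta_g1 = 0.5, mean_beta_g2 = 0.1,
    delta = c(0.4, 0.4, 0.4, 0.4, -0.4),
    p_value = 1e-5, fdr = 1e-4, significant = TRUE,
    stringsAsFactors = FALSE)

  dmrs <- call_dmrs(dmps[1:3, ], ann)
  expect_equal(nrow(dmrs), 1)  # {a,b} merge; c is a dropped singleton
  expect_equal(dmrs$n_probes, 2)
  expect_equal(dmrs$start, 99)   # 0-based half-open
  expect_equal(dmrs$end, 600)

  # d and e are within 1 kb but in opposite directions: never merged
  expect_equal(nrow(call_dmrs(dmps[4:5, ], ann)), 0)

  none <- dmps[0, ]
  expect_equal(nrow(call_dmrs(none, ann)), 0)
})

test_that("promoter methylation is the per-gene median over promoter probes", {
  probes <- c("p1", "p2", "p3", "p4")
  beta <- matrix(c(0.1, 0.2, 0.9, 0.5), 4, 2,
                 dimnames = list(probes, c("s1", "s2")))
  beta[, 2] <- c(0.3, 0.3, 0.3, 0.8)
  ann <- data.frame(
    probe_id = probes, chrom = "chr1", pos = 1:4 * 100L,
    gene = c("G1", "G1", "G1", "G2"),
    promoter_class = c("TSS200", "TSS1500", "1stExon", "TSS200"),
    cgi_relation = "island", enhancer_flag = FALSE, dnase_flag = FALSE,
    stringsAsFactors = FALSE)
  gm <- gene_promoter_beta(beta, ann)
  expect_equal(gm["G1", "s1"], 0.2)   # median of 0.1 / 0.2 / 0.9
  expect_equal(gm["G2", "s1"], 0.5)   # single probe passes through
  expect_equal(gm["G2", "s2"], 0.8)
})

test_that("frequently methylated genes match a hand-traced 5-gene fixture", {
  genes <- paste0("G", 1:5)
  tumors <- matrix(0.05, 5, 10, dimnames = list(genes, paste0("t", 1:10)))
  normals <- matrix(0.05, 5, 4, dimnames = list(genes, paste0("n", 1:4)))
  # G1: methylated in 3/10 tumors, clean normals -> reported (freq 0.3)
  tumors["G1", 1:3] <- 0.6
  # G2: methylated in 2/10 tumors, clean normals -> reported (freq 0.2)
  tumors["G2", 1:2] <- 0.45
  # G3: strong in tumors but >50% of normals >= 0.2 -> excluded
  tumors["G3", 1:8] <- 0.7
  normals["G3", 1:3] <- 0.25
  # G4: normal median >= 0.2 -> excluded
  tumors["G4", 1:5] <- 0.7
  normals["G4", ] <- c(0.25, 0.25, 0.15, 0.15)  # median 0.2 -> excluded
  # G5: passes normals but only 1/10 tumors -> frequency 0.1 not > 0.1
  tumors["G5", 1] <- 0.9

  out <- frequently_methylated_genes(tumors, normals)
  expect_setequal(out$gene, c("G1", "G2"))
  expect_equal(out$frequency[out$gene == "G1"], 0.3)
  expect_setequal(attr(out, "filtered_universe"), c("G1", "G2", "G5"))

  # spreadsheet-style recomputation of the same fixture
  keep <- vapply(genes, function(g) {
    !(mean(normals[g, ] >= 0.2) > 0.5 || median(normals[g, ]) >= 0.2)
  }, logical(1))
  manual <- genes[keep][colMeans(t(tumors[keep, ]) >= 0.3) > 0.1]
  expect_setequal(out$gene, manual)

  expect_equal(nrow(frequently_methylated_genes(tumors * 0, normals)), 0)
  expect_warning(frequently_methylated_genes(tumors), "normal")
})

test_that("genomic-context enrichment is null for subset == universe and flags a planted category", {
  fx <- toy_beta_fixture()
  universe <- fx$annotation$probe_id
  full <- genomic_context_enrichment(universe, universe, fx$annotation)
  expect_true(all(full$p_value == 1))
  expect_equal(full$subset_fraction, full$universe_fraction)

  enh <- fx$annotation$probe_id[fx$annotation$enhancer_flag]
  planted <- genomic_context_enrichment(enh, universe, fx$annotation)
  expect_equal(planted$category[which.min(planted$p_value)], "enhancer")
})

test_that("MeTIL-style score is zero on constant input and separates shifted groups", {
  beta <- matrix(0.5, 5, 6, dimnames = list(paste0("cg", 1:5), paste0("s", 1:6)))
  expect_equal(unname(metil_score(beta, paste0("cg", 1:5))), rep(0, 6))
  expect_error(metil_score(beta, "cg1"), "at least 2")

  set.seed(3)
  shifted <- beta + matrix(rnorm(30, 0, 0.01), 5)
  shifted[, 1:3] <- shifted[, 1:3] + 0.3
  shifted <- pmin(pmax(shifted, 0), 1)
  score <- metil_score(shifted, paste0("cg", 1:5))
  groups <- rep(1:2, each = 3)
  expect_equal(mclust::adjustedRandIndex(score > 0, groups), 1)
  expect_true(all(score[1:3] > 0))  # higher methylation of the set -> higher score
})
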