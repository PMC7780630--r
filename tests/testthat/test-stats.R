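test_that("Fisher exact matches exhaustive enumeration on representative tables", {
  tabs <- list(matrix(c(16, 7, 1, 11), 2, byrow = TRUE),
               matrix(c(5, 5, 5, 15), 2, byrow = TRUE),
               matrix(c(0, 10, 10, 0), 2, byrow = TRUE),
               matrix(c(3, 3, 3, 3), 2, byrow = TRUE))
  for (tab in tabs) {
    for (alt in c("two_sided", "less", "greater")) {
      expect_equal(fisher_exact(tab, alt)$p_value,
                   fisher_enum_oracle(tab, alt), tolerance = 1e-9)
    }
  }
  # the muscle-invasive enrichment table (16/23 vs 1/12): p ~ 9.4e-4
  expect_equal(fisher_exact(tabs[[1]])$p_value, 0.000944965, tolerance = 1e-6)
})

test_that("Fisher handles degenerate and zero-cell tables", {
  same <- matrix(c(4, 6, 4, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact(same)$p_value, 1)

  empty_margin <- matrix(c(0, 0, 5, 5), 2, byrow = TRUE)
  res <- fisher_exact(empty_margin)
  expect_equal(res$p_value, 1)
  expect_true(res$or_undefined)

  zero_cell <- matrix(c(8, 0, 2, 10), 2, byrow = TRUE)
  res2 <- fisher_exact(zero_cell)
  expect_false(res2$or_undefined)
  expect_true(is.finite(res2$log2_odds_ratio))  # Haldane correction applied
  expect_equal(res2$odds_ratio, (8.5 * 10.5) / (0.5 * 2.5))

  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("Mann-Whitney: exact enumeration on small samples, including ties", {
  # identical multisets: no evidence either way
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # complete separation of 3 vs 3: one-sided p = 1 / C(6,3)
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(res$p_value, 1 / 20)
  expect_equal(res$U, 0)

  # tie-heavy small fixture: exact path handles ties by construction
  x <- c(1, 1, 2, 2); y <- c(1, 2, 2, 3)
  res2 <- mann_whitney(x, y, "two_sided")
  expect_equal(res2$method, "exact enumeration")
  expect_gte(res2$p_value, 0)
  expect_lte(res2$p_value, 1)
})

test_that("the large-sample normal approximation agrees with a permutation oracle under ties", {
  set.seed(8)
  x <- sample(rep(1:5, times = c(10, 8, 9, 7, 6)))
  y <- sample(rep(1:5, times = c(8, 9, 7, 9, 7)))
  res <- mann_whitney(x, y, "greater")
  expect_match(res$method, "normal")

  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  set.seed(1)
  perm <- replicate(1e5, {
    idx <- sample(length(pooled), nx)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p_perm <- mean(perm >= u_obs - 1e-9)
  expect_equal(res$p_value, p_perm, tolerance = 0.005)
})

test_that("BH adjustment reproduces the step-up hand computation and its properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= min(p)))
  flat <- rep(0.04, 4)
  expect_equal(bh_fdr(flat), flat)  # step-up fixed point on a flat vector
})

test_that("log-rank matches the hand-computed observed-minus-expected statistic", {
  clin <- data.frame(
    sample_id = paste0("s", 1:6),
    os_time = c(6, 7, 10, 15, 19, 25),
    os_event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  grp <- c("A", "B", "A", "B", "A", "B")
  res <- km_logrank(clin, grp, "os")
  expect_equal(res$chisq, logrank_oracle(clin$os_time, clin$os_event, grp),
               tolerance = 1e-8)
  expect_equal(res$df, 1)

  # identical groups: statistic 0, p = 1
  clin2 <- rbind(clin, clin)
  grp2 <- rep(c("A", "B"), each = 6)
  clin2$sample_id <- paste0("s", 1:12)
  res2 <- km_logrank(clin2, grp2, "os")
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-8)
})

test_that("the KM estimate without censoring equals the empirical survival function", {
  times <- c(2, 5, 5, 9, 12)
  clin <- data.frame(os_time = times, os_event = TRUE)
  fit <- survival::survfit(survival::Surv(times, rep(1, 5)) ~ 1)
  ecdf_surv <- vapply(fit$time, function(t) mean(times > t), numeric(1))
  expect_equal(fit$surv, ecdf_surv)
})

test_that("Cox recovery: consistent for a true HR, flags separation, rejects constants", {
  sim_one <- function(seed, n = 500, hr = 3) {
    set.seed(seed)
    grp <- rep(0:1, each = n / 2)
    t_ev <- rexp(n, rate = 0.05 * hr^grp)
    cens <- rexp(n, rate = 0.005)
    data.frame(os_time = pmin(t_ev, cens), os_event = t_ev <= cens, grp = grp)
  }
  loghrs <- vapply(1:20, function(s) {
    d <- sim_one(s)
    cox_univariate(d, d$grp, "os")$log_hr
  }, numeric(1))
  expect_lt(abs(mean(loghrs) - log(3)) / log(3), 0.10)

  sep <- data.frame(os_time = c(1, 2), os_event = c(TRUE, TRUE))
  res <- cox_univariate(sep, c(1, 0), "os")
  expect_true(res$separated)
  expect_true(is.na(res$hr))

  expect_error(cox_univariate(sep, c(1, 1), "os"), "vary")
})

test_that("expression filtering applies the >=90% low-expression rule then transforms", {
  fpkm <- matrix(1.5, 4, 10, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  fpkm["g1", ] <- 0                      # low everywhere: dropped
  fpkm["g2", 1:9] <- 0.5                 # low in exactly 90%: dropped (>= rule)
  fpkm["g3", 1:8] <- 0.5                 # low in 80%: kept
  out <- expression_filter(fpkm)
  expect_setequal(rownames(out), c("g3", "g4"))
  # median-centered in both directions after log2
  expect_equal(unname(apply(out, 2, median)), rep(0, 10))
  expect_error(expression_filter(fpkm - 5), ">= 0")
})

test_that("nearest-centroid classification follows the highest correlation", {
  set.seed(12)
  centroids <- matrix(rnorm(40), 20, 2,
                      dimnames = list(paste0("g", 1:20), c("classA", "classB")))
  expr <- cbind(s1 = centroids[, 1], s2 = -centroids[, 1],
                s3 = centroids[, 2] + rnorm(20, 0, 0.1), s4 = rep(1, 20))
  rownames(expr) <- rownames(centroids)
  res <- nearest_centroid_classify(expr, centroids)
  expect_equal(res$label[res$sample_id == "s1"], "classA")
  expect_equal(res$best_cor[res$sample_id == "s1"], 1)
  expect_equal(res$label[res$sample_id == "s2"], "classB")  # negation flips class
  expect_equal(res$label[res$sample_id == "s3"], "classB")
  expect_true(is.na(res$label[res$sample_id == "s4"]))      # zero variance

  expect_error(nearest_centroid_classify(expr[1, , drop = FALSE], centroids),
               "shared genes")
})

test_that("signature scores are centered for the full set and separate a planted shift", {
  set.seed(5)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  all_score <- signature_score(expr, rownames(expr), "mean_z")
  expect_equal(unname(rowSums(scale(t(expr)))) / 20, unname(all_score),
               tolerance = 1e-8)
  expect_equal(mean(all_score), 0, tolerance = 1e-12)  # z-scores average out

  planted <- paste0("g", 1:6)
  expr2 <- expr
  expr2[planted, 1:5] <- expr2[planted, 1:5] + 3
  sc <- signature_score(expr2, planted, "mean_z")
  expect_true(all(sc[1:5] > 0) && all(sc[6:10] < 0))

  ss <- signature_score(expr2, planted, "rank_ssgsea")
  expect_true(mean(ss[1:5]) > mean(ss[6:10]))
  expect_error(signature_score(expr, c("nope"), "mean_z"), "intersect")
})
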