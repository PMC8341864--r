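test_that("cluster significance separates real clusters from one Gaussian", {
  set.seed(60)
  # two clearly separated Gaussians: p at the resolution floor
  Z <- cbind(matrix(rnorm(2 * 40), 2, 40), matrix(rnorm(2 * 40) + 10, 2, 40))
  colnames(Z) <- sprintf("s%02d", 1:80)
  lv <- label_vector(colnames(Z), rep(c("a", "b"), each = 40))
  p <- sigclust_pairwise(Z, lv, n_sim = 199, seed = 1)
  expect_equal(p["a", "b"], 1 / 200)
  expect_true(is.na(p["a", "a"]))

  # tiny classes are flagged, not tested
  lv2 <- label_vector(colnames(Z), c(rep("a", 2), rep("b", 78)))
  expect_warning(p2 <- sigclust_pairwise(Z, lv2, n_sim = 100, seed = 1),
                 "fewer than 3")
  expect_true(is.na(p2["a", "b"]))
  expect_error(sigclust_pairwise(Z, lv, n_sim = 10), ">= 100")
})

test_that("silhouette scores behave across geometry and labelings", {
  b <- blob_fused(n_per = 40)
  expect_gt(silhouette_score(b$Z, b$labels), 0.9)

  # random labels on one Gaussian: near zero
  set.seed(61)
  Z <- matrix(rnorm(3 * 500), 3, 500, dimnames = list(NULL, sprintf("s%03d", 1:500)))
  lv <- label_vector(colnames(Z), sample(1:3, 500, replace = TRUE))
  s <- silhouette_score(Z, lv)
  expect_lt(abs(s), 0.05)
  expect_gte(s, -1); expect_lte(s, 1)

  # invariant under rotation and translation of the fused space
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
  Z2 <- R %*% Z + 5
  colnames(Z2) <- colnames(Z)
  expect_equal(silhouette_score(Z2, lv), s, tolerance = 1e-10)

  expect_error(silhouette_score(Z, label_vector(colnames(Z), rep(1, 500))),
               "at least 2")
})

test_that("hypergeometric association is exact and monotone in the overlap", {
  ids <- sprintf("s%02d", 1:20)
  l1 <- label_vector(ids, rep(c("A", "B"), each = 10))
  res <- association_test(l1, l1)
  expect_equal(res$p_values["A", "A"], 1 / choose(20, 10), tolerance = 1e-13)
  expect_equal(res$p_values["B", "B"], 1 / choose(20, 10), tolerance = 1e-13)
  # perfectly symmetric confusion table: no asymmetry signal
  expect_equal(res$bowker$statistic, 0)
  expect_equal(res$bowker$p_value, 1)

  # monotonicity: larger overlap at fixed margins -> smaller p
  p_at_overlap <- vapply(5:10, function(o) {
    phyper(o - 1, 10, 10, 10, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p_at_overlap) < 0))

  l3 <- label_vector(sprintf("x%02d", 1:20), rep(c("A", "B"), each = 10))
  expect_error(association_test(l1, l3), "different samples")
})

test_that("a symmetric off-diagonal disagreement pattern yields Bowker 0", {
  ids <- sprintf("s%02d", 1:14)
  l1 <- label_vector(ids, c(rep("a", 5), rep("b", 5), "a", "a", "b", "b"))
  l2 <- label_vector(ids, c(rep("a", 5), rep("b", 5), "b", "b", "a", "a"))
  res <- association_test(l1, l2)
  expect_equal(res$overlap_counts, matrix(c(5, 2, 2, 5), 2, 2,
               dimnames = dimnames(res$overlap_counts)))
  expect_equal(res$bowker$statistic, 0)
  expect_equal(res$bowker$p_value, 1)
})

test_that("independent labelings rarely reach the association significance bar", {
  set.seed(62)
  hits <- replicate(200, {
    ids <- sprintf("s%03d", 1:120)
    l1 <- label_vector(ids, sample(1:4, 120, replace = TRUE))
    l2 <- label_vector(ids, sample(1:4, 120, replace = TRUE))
    res <- association_test(l1, l2, p_adjust = "bonferroni")
    min(res$p_values) < 0.001
  })
  expect_gte(mean(!hits), 0.95)
})

test_that("log-rank testing detects real hazard differences and rejects bad input", {
  set.seed(63)
  n <- 100
  ids <- sprintf("s%03d", 1:(2 * n))
  time <- c(rexp(n, 0.1), rexp(n, 0.3))          # hazard ratio 3
  event <- rbinom(2 * n, 1, 0.8)
  cl <- clinical_table(ids, time, event)
  lv <- label_vector(ids, rep(c("lo", "hi"), each = n))
  res <- logrank_by_subtype(cl, lv)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$df, 1)
  expect_named(res$km)
  expect_true(all(vapply(res$km, function(t) all(diff(t$surv) <= 1e-12), logical(1))))

  # power at hazard ratio 3 (modest replicate count for speed)
  rej <- replicate(30, {
    t2 <- c(rexp(n, 0.1), rexp(n, 0.3))
    e2 <- rbinom(2 * n, 1, 0.8)
    logrank_by_subtype(clinical_table(ids, t2, e2), lv)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.9)

  expect_error(logrank_by_subtype(clinical_table(ids, time, rep(0, 2 * n)), lv),
               "censored")
  lv_empty <- label_vector(ids, factor(rep(c("lo", "hi"), each = n),
                                       levels = c("lo", "hi", "ghost")))
  expect_equal(nlevels(lv_empty$labels), 3)  # empty level preserved
  expect_error(logrank_by_subtype(cl, lv_empty), "empty group")
})

test_that("canonical variate supports correlate while random pairs do not", {
  coh <- simulate_cohort(n = 200, D_a = 100, D_b = 100, k_subtypes = 2,
                         m_latent = 1, support_size = 10, effect_size = 3,
                         noise_sd_a = 0.05, noise_sd_b = 0.05,
                         hazard_ratios = c(1, 2), seed = 64)
  A <- zscore_features(coh$mrna); B <- zscore_features(coh$mirna)
  fit <- scca(A, B, n_components = 1)
  vc <- variate_pair_correlations(fit, coh$mrna, coh$mirna, component = 1,
                                  n_background = 200, seed = 2)
  expect_gt(mean(abs(vc$observed)), 0.9)            # near-noiseless shared factor
  expect_lt(abs(mean(vc$background)), 0.05)
  expect_equal(vc$n_pairs, length(vc$support_a) * length(vc$support_b))
  expect_error(variate_pair_correlations(fit, coh$mrna, coh$mirna,
                                         component = 5), "component")
})

test_that("background correlation distribution is centred at zero", {
  set.seed(65)
  coh <- simulate_cohort(n = 500, D_a = 80, D_b = 60, seed = 66,
                         support_size = 5)
  A <- zscore_features(coh$mrna); B <- zscore_features(coh$mirna)
  fit <- scca(A, B, n_components = 1)
  vc <- variate_pair_correlations(fit, coh$mrna, coh$mirna,
                                  n_background = 1000, seed = 3)
  expect_lt(abs(mean(vc$background)), 0.02)
})
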