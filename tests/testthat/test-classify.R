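quiet_predict <- function(expr) suppressMessages(expr)

test_that("nearest-centroid training is perfect on separable classes", {
  set.seed(50)
  ctr <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = 30)
  Z <- t(ctr[lab, ] + matrix(rnorm(90 * 2), 90, 2))
  colnames(Z) <- sprintf("s%02d", 1:90)
  lv <- label_vector(colnames(Z), lab)
  learner <- train_classifier(Z, lv, method = "mindis")
  pred <- sccaCC:::predict_learner(learner, Z)
  expect_equal(mean(as.character(pred) == as.character(lv$labels)), 1)
})

test_that("degenerate label configurations are rejected", {
  Z <- matrix(rnorm(20), 2, 10, dimnames = list(NULL, paste0("s", 1:10)))
  expect_error(train_classifier(Z, label_vector(paste0("s", 1:10), rep("a", 10))),
               "at least 2 classes")
  expect_error(train_classifier(Z, label_vector(paste0("s", 1:10),
                                                c(rep("a", 9), "b"))),
               "singleton.*b")
})

test_that("every classifier method trains and predicts its own classes", {
  set.seed(51)
  ctr <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = 20)
  Z <- t(ctr[lab, ] + matrix(rnorm(60 * 2), 60, 2))
  colnames(Z) <- sprintf("s%02d", 1:60)
  lv <- label_vector(colnames(Z), lab)
  for (m in c("rf", "svm", "knn", "mindis", "nbayes")) {
    learner <- train_classifier(Z, lv, method = m, seed = 4)
    pred <- sccaCC:::predict_learner(learner, Z)
    expect_true(all(as.character(pred) %in% learner$class_labels))
    expect_gt(mean(as.character(pred) == as.character(lv$labels)), 0.9)
  }
})

test_that("fused prediction reproduces training labels and permutes with samples", {
  coh <- small_cohort()
  fit <- suppressMessages(scca_cc(coh$mrna, coh$mirna, n_components = 5, k = 4,
                                  consensus_iter = 30, seed = 2))
  pred <- quiet_predict(predict_fused(fit, coh$mrna, coh$mirna))
  expect_gt(mean(as.character(pred$labels) == as.character(fit$labels$labels)), 0.95)

  perm <- sample(ncol(coh$mrna$values))
  permute <- function(v) omics_view(v$values[, perm], view_name = v$view_name)
  pred_perm <- quiet_predict(predict_fused(fit, permute(coh$mrna), permute(coh$mirna)))
  expect_identical(as.character(pred_perm$labels),
                   as.character(pred$labels)[perm])
})

test_that("alpha = 1 makes fused prediction identical to view-a prediction", {
  coh <- small_cohort()
  fit <- suppressMessages(scca_cc(coh$mrna, coh$mirna, n_components = 5, k = 4,
                                  alpha = 1, consensus_iter = 30, seed = 2))
  pf <- quiet_predict(predict_fused(fit, coh$mrna, coh$mirna))
  ps <- quiet_predict(predict_single(fit, coh$mrna, "a"))
  expect_identical(as.character(pf$labels), as.character(ps$labels))
})

test_that("duplicate views make single-view and fused predictions coincide", {
  # both views observe the same signal with vanishing noise
  coh <- simulate_cohort(n = 100, D_a = 60, D_b = 60, k_subtypes = 3,
                         m_latent = 2, support_size = 6, effect_size = 4,
                         noise_sd_a = 1e-3, noise_sd_b = 1e-3,
                         hazard_ratios = c(1, 2, 1), seed = 12)
  fit <- suppressMessages(scca_cc(coh$mrna, coh$mirna, n_components = 2, k = 3,
                                  consensus_iter = 30, seed = 3))
  pf <- quiet_predict(predict_fused(fit, coh$mrna, coh$mirna))
  pa <- quiet_predict(predict_single(fit, coh$mrna, "a"))
  pb <- quiet_predict(predict_single(fit, coh$mirna, "b"))
  expect_gt(mean(pf$labels == pa$labels), 0.97)
  expect_gt(mean(pf$labels == pb$labels), 0.97)
})

test_that("classifiers never see raw features: foreign features are ignored", {
  coh <- small_cohort()
  fit <- suppressMessages(scca_cc(coh$mrna, coh$mirna, n_components = 5, k = 4,
                                  consensus_iter = 30, seed = 2))
  base <- quiet_predict(predict_single(fit, coh$mrna, "a"))
  # adding a feature unknown to the projection must not change predictions
  aug <- omics_view(rbind(coh$mrna$values,
                          extra = rnorm(ncol(coh$mrna$values))),
                    view_name = "mrna")
  with_extra <- quiet_predict(predict_single(fit, aug, "a"))
  expect_identical(as.character(base$labels), as.character(with_extra$labels))
})

test_that("single-repetition holdout on separable data is perfect", {
  coh <- simulate_cohort(n = 90, D_a = 60, D_b = 40, k_subtypes = 3,
                         m_latent = 2, support_size = 6, effect_size = 8,
                         noise_sd_a = 0.2, noise_sd_b = 0.2,
                         hazard_ratios = c(1, 2, 1), seed = 13)
  rep1 <- suppressMessages(repeated_holdout(coh$mrna, coh$mirna,
                                            coh$truth$labels, n_train = 60,
                                            n_reps = 1, methods = "mindis",
                                            n_components = 3, seed = 5))
  expect_equal(unname(rep1$accuracy$mindis[1, ]), c(1, 1, 1))
})

test_that("holdout reports are reproducible and fused dominates under equal noise", {
  coh <- simulate_cohort(n = 150, D_a = 60, D_b = 60, k_subtypes = 4,
                         m_latent = 3, support_size = 6, effect_size = 3,
                         noise_sd_a = 0.7, noise_sd_b = 0.7, seed = 14)
  h1 <- suppressMessages(repeated_holdout(coh$mrna, coh$mirna, coh$truth$labels,
                                          n_train = 100, n_reps = 20,
                                          methods = "mindis", n_components = 5,
                                          seed = 6))
  h2 <- suppressMessages(repeated_holdout(coh$mrna, coh$mirna, coh$truth$labels,
                                          n_train = 100, n_reps = 20,
                                          methods = "mindis", n_components = 5,
                                          seed = 6))
  expect_identical(h1$accuracy, h2$accuracy)
  m <- colMeans(h1$accuracy$mindis)
  # with exchangeable views the fused input cannot lose (sampling slack 0.02)
  expect_gte(m["fused"], max(m["view_a"], m["view_b"]) - 0.02)
  expect_error(suppressMessages(
    repeated_holdout(coh$mrna, coh$mirna, coh$truth$labels,
                     n_train = 150, n_reps = 1)), "below")
})
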