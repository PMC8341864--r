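test_that("soft thresholding follows its closed form", {
  expect_equal(soft_threshold(c(3, -0.5, -2), 1), c(2, 0, -1))
  a <- c(-4, 0, 2.5, 1)
  expect_equal(soft_threshold(a, 0), a)          # identity at delta = 0
  expect_equal(soft_threshold(a, 4), rep(0, 4))  # delta >= max|a|
  expect_error(soft_threshold(a, -1), "non-negative")
})

test_that("l1-constrained unit maximizer handles slack, tight and one-hot budgets", {
  # constraint inactive: plain normalization
  expect_equal(l1_constrained_unit(c(3, 4), 1.4142), c(0.6, 0.8), tolerance = 1e-6)
  # c = 1: one-hot at the unique largest-magnitude entry
  expect_equal(l1_constrained_unit(c(3, 4), 1), c(0, 1), tolerance = 1e-6)
  expect_equal(l1_constrained_unit(c(-5, 2, 1), 1), c(-1, 0, 0), tolerance = 1e-6)
  # active constraint matches the brute-force grid maximizer
  u <- l1_constrained_unit(c(3, 4), 1.2)
  expect_equal(u, l1_grid_oracle(c(3, 4), 1.2), tolerance = 1e-6)
  expect_error(l1_constrained_unit(c(0, 0), 1), "degenerate")
  expect_error(l1_constrained_unit(c(1, 2), 0.5), "must lie in")
})

test_that("fitted directions always satisfy both norm constraints", {
  set.seed(11)
  for (i in 1:25) {
    p <- sample(3:40, 1)
    a <- rnorm(p)
    c_ <- runif(1, 1, sqrt(p))
    u <- l1_constrained_unit(a, c_)
    expect_lte(sum(u^2), 1 + 1e-6)
    expect_lte(sum(abs(u)), c_ + 1e-6)
  }
})

test_that("rank-1 decomposition reduces to the leading singular triple without sparsity", {
  set.seed(20)
  K <- matrix(rnorm(20 * 15), 20, 15)
  out <- pmd_rank1(K, sqrt(20), sqrt(15))
  sv <- svd(K)
  s <- sign(sum(out$u * sv$u[, 1]))
  expect_equal(out$u, s * sv$u[, 1], tolerance = 1e-8)
  expect_equal(out$v, s * sv$v[, 1], tolerance = 1e-8)
  expect_equal(out$d, sv$d[1], tolerance = 1e-8)
})

test_that("rank-1 decomposition recovers an exact rank-1 matrix", {
  u0 <- c(1, 2, -2) / 3
  v0 <- c(3, 0, 4, 0) / 5
  K <- 3 * tcrossprod(u0, v0)
  out <- pmd_rank1(K, sqrt(3), sqrt(4))
  s <- sign(sum(out$u * u0))
  expect_equal(out$u, s * u0, tolerance = 1e-10)
  expect_equal(out$v, s * v0, tolerance = 1e-10)
  expect_equal(out$d, 3, tolerance = 1e-10)
})

test_that("the alternation objective is non-decreasing", {
  set.seed(21)
  for (i in 1:5) {
    K <- matrix(rnorm(30 * 12), 30, 12)
    out <- pmd_rank1(K, runif(1, 1, sqrt(30)), runif(1, 1, sqrt(12)))
    # monotone up to the inner bisection tolerance on the L1 norm
    expect_true(all(diff(out$objective) >= -1e-6 * max(abs(out$objective))))
  }
  expect_warning(z <- pmd_rank1(matrix(0, 3, 3), 1, 1), "zero")
  expect_equal(z$d, 0)
})

test_that("scca in the no-sparsity limit matches the SVD of the cross-product", {
  set.seed(30)
  mk <- function(D, n, prefix) {
    zscore_features(omics_view(matrix(rnorm(D * n), D, n,
      dimnames = list(paste0(prefix, 1:D), paste0("s", 1:n)))))
  }
  A <- mk(30, 40, "g")
  B <- mk(25, 40, "m")
  fit <- scca(A, B, penalty_a = 1, penalty_b = 1, n_components = 5)
  sv <- svd(A$values %*% t(B$values))
  expect_equal(fit$d, sv$d[1:5], tolerance = 1e-6)
  for (k in 1:3) {
    s <- sign(sum(fit$P_a[, k] * sv$u[, k]))
    expect_equal(unname(fit$P_a[, k]), s * sv$u[, k], tolerance = 1e-5)
  }
})

test_that("deflation residual shrinks as components accumulate", {
  set.seed(31)
  mk <- function(D, n, prefix) zscore_features(omics_view(matrix(rnorm(D * n), D, n,
    dimnames = list(paste0(prefix, 1:D), paste0("s", 1:n)))))
  A <- mk(15, 30, "g"); B <- mk(12, 30, "m")
  fit <- scca(A, B, penalty_a = 1, penalty_b = 1, n_components = 10)
  K <- A$values %*% t(B$values)
  res <- vapply(1:10, function(m) {
    R <- K
    for (k in 1:m) R <- R - fit$d[k] * tcrossprod(fit$P_a[, k], fit$P_b[, k])
    sqrt(sum(R^2))
  }, numeric(1))
  expect_true(all(diff(res) < 1e-8))
})

test_that("identical views give a perfectly correlated first variate pair", {
  set.seed(32)
  v <- zscore_features(omics_view(matrix(rnorm(200), 10, 20,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))))
  fit <- scca(v, v, penalty_a = 1, penalty_b = 1, n_components = 1)
  A_P <- project(fit$P_a, v)
  B_P <- project(fit$P_b, v)
  expect_equal(cor(A_P[1, ], B_P[1, ]), 1, tolerance = 1e-8)
})

test_that("scca fits are deterministic and respect the penalty contract", {
  coh <- small_cohort()
  A <- zscore_features(coh$mrna); B <- zscore_features(coh$mirna)
  f1 <- scca(A, B, n_components = 5)
  f2 <- scca(A, B, n_components = 5)
  expect_identical(f1, f2)
  c1 <- 0.3 * sqrt(nrow(A$values)); c2 <- 0.3 * sqrt(nrow(B$values))
  expect_true(all(colSums(f1$P_a^2) <= 1 + 1e-6))
  expect_true(all(colSums(abs(f1$P_a)) <= c1 + 1e-6))
  expect_true(all(colSums(abs(f1$P_b)) <= c2 + 1e-6))
  expect_true(all(f1$d >= 0))
  expect_error(scca(A, B, penalty_a = 0), "penalties")
  expect_error(scca(A, B, penalty_a = 1.2), "penalties")
  b2 <- omics_view(B$values[, rev(seq_len(ncol(B$values)))], view_name = "m")
  expect_error(scca(A, b2), "aligned")
})

test_that("projection is exact and sample-permutation equivariant", {
  set.seed(33)
  v <- tiny_view(matrix(rnorm(6), 3, 2))
  P <- diag(3)
  rownames(P) <- v$feature_ids
  expect_equal(unname(project(P, v)), unname(v$values))
  # permutation equivariance
  v2 <- omics_view(v$values[, 2:1], view_name = "test")
  P2 <- matrix(rnorm(6), 3, 2, dimnames = list(v$feature_ids, c("CV1", "CV2")))
  expect_equal(project(P2, v2), project(P2, v)[, 2:1])
  # single-column view: plain dot products
  v1 <- omics_view(v$values[, 1, drop = FALSE], view_name = "test")
  expect_equal(unname(project(P2, v1)[, 1]), unname(crossprod(P2, v$values[, 1])[, 1]))
  expect_error(project(P2[1:2, ], v), "features")
})

test_that("fusion blends projections by its coefficient", {
  set.seed(34)
  A_P <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  B_P <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_identical(fuse(A_P, B_P, 1)$Z, A_P)        # alpha = 1 -> view a
  expect_lt(max(abs(fuse(A_P, A_P, 0.3)$Z - A_P)), 1e-12)  # equal inputs
  f <- fuse(A_P, B_P, 0.5)
  expect_equal(f$Z, 0.5 * A_P + 0.5 * B_P)
  expect_error(fuse(A_P, B_P, 1.5), "alpha")
  expect_error(fuse(A_P, B_P[, 1:3], 0.5), "shape")
})
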