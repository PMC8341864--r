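#' Soft-thresholding operator
#'
#' `sign(a) * pmax(|a| - delta, 0)`, the proximal operator of the lasso
#' penalty used inside the penalized matrix decomposition.
#'
#' @param a Numeric vector.
#' @param delta Non-negative threshold.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' soft_threshold(c(3, -0.5, -2), 1) # 2, 0, -1
soft_threshold <- function(a, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stopf("delta must be a single non-negative number")
  sign(a) * pmax(abs(a) - delta, 0)
}

#' L1-constrained unit-norm maximizer
#'
#' Solves `argmax_u u'a` subject to `||u||_2 <= 1` and `||u||_1 <= c`.
#' The solution is `S(a, delta) / ||S(a, delta)||_2` where `S` is
#' [soft_threshold()] and `delta >= 0` is found by bisection (`delta = 0`
#' when the L1 constraint is already slack).  This is the inner step of
#' the penalized matrix decomposition behind sparse CCA.
#'
#' @param a Numeric vector, not all zero.
#' @param c L1 budget in `[1, sqrt(length(a))]`; `c = 1` yields a
#'   one-hot vector, `c = sqrt(length(a))` makes the constraint inactive.
#' @return Unit-L2 vector with `||u||_1 <= c` (up to 1e-8).
#' @export
l1_constrained_unit <- function(a, c) {
  a <- as.numeric(a)
  if (all(a == 0)) stopf("degenerate direction: input vector is all zero")
  if (!is.numeric(c) || length(c) != 1 || c < 1 || c > sqrt(length(a)) + 1e-12)
    stopf("c must lie in [1, sqrt(length(a))]")
  .cpp_l1_constrained_unit(a, c)
}

#' Rank-1 penalized matrix decomposition
#'
#' Alternating maximization of `u'Kv` under unit-L2 and L1 constraints on
#' both factors, starting deterministically from the leading right
#' singular vector of `K`.  Each half-step is an exact
#' [l1_constrained_unit()] update, so the objective is non-decreasing
#' across iterations.
#'
#' @param K Numeric matrix (p x q), finite.
#' @param c1,c2 L1 budgets for `u` (length p) and `v` (length q).
#' @param max_iter Maximum number of alternations.
#' @param tol Convergence threshold on the relative L2 change of `v`.
#' @return A list with unit vectors `u`, `v`, the value `d = u'Kv >= 0`,
#'   the iteration count and the per-iteration `objective` trace.  A
#'   zero matrix yields zero vectors and `d = 0` with a warning.
#' @export
pmd_rank1 <- function(K, c1, c2, max_iter = 200, tol = 1e-6) {
  K <- as.matrix(K)
  if (!all(is.finite(K))) stopf("K must be finite")
  if (all(K == 0)) {
    warnf("K is identically zero; returning zero factors")
    return(list(u = numeric(nrow(K)), v = numeric(ncol(K)), d = 0,
                iterations = 0L, objective = numeric(0)))
  }
  p <- nrow(K); q <- ncol(K)
  if (c1 < 1 || c1 > sqrt(p) + 1e-12) stopf("c1 must lie in [1, sqrt(nrow(K))]")
  if (c2 < 1 || c2 > sqrt(q) + 1e-12) stopf("c2 must lie in [1, sqrt(ncol(K))]")
  v0 <- svd(K, nu = 0, nv = 1)$v[, 1]
  out <- .cpp_pmd_rank1(K, v0, c1, c2, as.integer(max_iter), tol)
  # deterministic orientation: largest-magnitude entry of u positive
  i <- which.max(abs(out$u))
  if (length(i) && out$u[i] < 0) {
    out$u <- -out$u
    out$v <- -out$v
  }
  out
}

#' Sparse canonical correlation analysis of two omics views
#'
#' Fits an L1-penalized rank-`n_components` decomposition of the
#' cross-product matrix `K = A B'` (within-view covariances treated as
#' identity, the diagonal-penalized CCA convention that makes the
#' problem well-posed when features far outnumber samples).  Component
#' `k` maximizes `u'Kv` under `||u||_1 <= penalty_a * sqrt(D_a)` (and
#' likewise for `v`), after which `K` is deflated by `d_k u_k v_k'`.
#' The columns of the returned projection matrices are the canonical
#' vectors: sparse feature loadings whose variates (projected sample
#' coordinates) are maximally correlated across views.
#'
#' Views must be sample-aligned and feature-standardized (see
#' [zscore_features()] and [align_samples()]).
#'
#' @param A,B [omics_view] objects with identical sample ids in
#'   identical order.
#' @param penalty_a,penalty_b Sparsity penalties in (0, 1]; the L1
#'   budget of a canonical vector is `penalty * sqrt(D)`.  Default 0.3.
#' @param n_components Number of canonical vector pairs; defaults to the
#'   lower of the two feature counts, capped at `n - 1` (the rank bound)
#'   with a warning.  Components with `d < 1e-10` are dropped.
#' @param max_iter,tol Alternation control, see [pmd_rank1()].
#' @return An object of class `scca`: projection matrices `P_a`
#'   (`D_a x m`) and `P_b`, canonical values `d`, feature ids, the
#'   penalty configuration and per-component iteration counts.  The fit
#'   is fully deterministic.
#' @seealso [project()], [fuse()], [predict.scca()]
#' @export
scca <- function(A, B, penalty_a = 0.3, penalty_b = 0.3, n_components = NULL,
                 max_iter = 200, tol = 1e-6) {
  if (!inherits(A, "omics_view") || !inherits(B, "omics_view"))
    stopf("A and B must be omics_view objects")
  if (!identical(A$sample_ids, B$sample_ids))
    stopf("views are not sample-aligned; call align_samples() first")
  for (p in c(penalty_a, penalty_b))
    if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
      stopf("penalties must lie in (0, 1]")
  Da <- nrow(A$values); Db <- nrow(B$values); n <- ncol(A$values)
  m <- n_components %||% min(Da, Db)
  if (m < 1) stopf("n_components must be >= 1")
  if (m > n - 1) {
    warnf("n_components %d exceeds the rank bound n - 1 = %d; capping", m, n - 1)
    m <- n - 1
  }
  m <- min(m, Da, Db)
  c1 <- penalty_a * sqrt(Da)
  c2 <- penalty_b * sqrt(Db)
  if (c1 < 1) { warnf("penalty_a * sqrt(D_a) = %.3f < 1; using 1", c1); c1 <- 1 }
  if (c2 < 1) { warnf("penalty_b * sqrt(D_b) = %.3f < 1; using 1", c2); c2 <- 1 }

  K <- A$values %*% t(B$values)
  P_a <- matrix(0, Da, m); P_b <- matrix(0, Db, m)
  d <- numeric(m); iters <- integer(m)
  kept <- 0L
  for (k in seq_len(m)) {
    if (all(abs(K) < 1e-12)) break
    v0 <- svd(K, nu = 0, nv = 1)$v[, 1]
    out <- .cpp_pmd_rank1(K, v0, c1, c2, as.integer(max_iter), tol)
    if (out$d < 1e-10) break
    i <- which.max(abs(out$u))
    if (out$u[i] < 0) { out$u <- -out$u; out$v <- -out$v }
    kept <- k
    P_a[, k] <- out$u; P_b[, k] <- out$v
    d[k] <- out$d; iters[k] <- out$iterations
    K <- K - out$d * tcrossprod(out$u, out$v)
  }
  if (kept < m) {
    warnf("stopping after %d component(s): residual cross-product exhausted", kept)
    if (kept == 0L) stopf("no canonical component could be extracted")
    P_a <- P_a[, seq_len(kept), drop = FALSE]
    P_b <- P_b[, seq_len(kept), drop = FALSE]
    d <- d[seq_len(kept)]; iters <- iters[seq_len(kept)]
  }
  comp <- paste0("CV", seq_len(ncol(P_a)))
  dimnames(P_a) <- list(A$feature_ids, comp)
  dimnames(P_b) <- list(B$feature_ids, comp)
  structure(list(P_a = P_a, P_b = P_b, d = d,
                 feature_ids_a = A$feature_ids, feature_ids_b = B$feature_ids,
                 view_names = c(A$view_name, B$view_name),
                 config = list(penalty_a = penalty_a, penalty_b = penalty_b,
                               n_components = ncol(P_a), max_iter = max_iter,
                               tol = tol),
                 iterations = iters, n = n),
            class = "scca")
}

#' @export
print.scca <- function(x, ...) {
  cat(sprintf("sparse CCA: %d canonical vector pairs (%s: %d features, %s: %d features)\n",
              ncol(x$P_a), x$view_names[1], nrow(x$P_a),
              x$view_names[2], nrow(x$P_b)))
  cat(sprintf("penalties %.2f/%.2f; non-zero loadings per component:\n",
              x$config$penalty_a, x$config$penalty_b))
  nz <- rbind(colSums(x$P_a != 0), colSums(x$P_b != 0))
  rownames(nz) <- x$view_names
  print(utils::head(t(nz), 10))
  invisible(x)
}

#' @export
#' @describeIn scca returns the loading matrix of one view
#'   (`view = "a"` or `"b"`).
coef.scca <- function(object, view = c("a", "b"), ...) {
  view <- match.arg(view)
  if (view == "a") object$P_a else object$P_b
}

#' Project a view onto canonical variates
#'
#' Computes `P' X`, the coordinates of every sample in the unified
#' space.  `P` may be a bare loading matrix or an `scca` fit, in which
#' case `which` selects the view.
#'
#' @param P A `D x m` loading matrix with feature ids as row names, or
#'   an [scca] object.
#' @param X An [omics_view] whose features match `P`'s rows exactly (use
#'   [align_features()] first if they do not).
#' @param which For an `scca` fit, `"a"` or `"b"`.
#' @return An `m x n` matrix of canonical variates (components x samples).
#' @export
project <- function(P, X, which = c("a", "b")) {
  if (inherits(P, "scca")) {
    which <- match.arg(which)
    P <- if (which == "a") P$P_a else P$P_b
  }
  P <- as.matrix(P)
  if (!inherits(X, "omics_view")) stopf("X must be an omics_view")
  if (nrow(P) != nrow(X$values))
    stopf("projection has %d rows but view has %d features", nrow(P), nrow(X$values))
  if (!is.null(rownames(P)) && !identical(rownames(P), X$feature_ids))
    stopf("feature ids of the view do not match the projection; call align_features()")
  Z <- crossprod(P, X$values)
  rownames(Z) <- colnames(P)
  Z
}

#' Fuse two projected views by weighted averaging
#'
#' `Z = alpha * A_P + (1 - alpha) * B_P`, the unified multi-omics
#' representation used for clustering and classification.
#'
#' @param A_P,B_P `m x n` canonical variate matrices from [project()].
#' @param alpha Fusion coefficient in `[0, 1]`; 0.5 (the default) weighs
#'   both omics types equally.
#' @return An object of class `fused_repr` with elements `A_P`, `B_P`,
#'   `Z`, `alpha` and `sample_ids`.
#' @export
fuse <- function(A_P, B_P, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stopf("alpha must lie in [0, 1]")
  A_P <- as.matrix(A_P); B_P <- as.matrix(B_P)
  if (!all(dim(A_P) == dim(B_P))) stopf("A_P and B_P must have identical shape")
  Z <- alpha * A_P + (1 - alpha) * B_P
  structure(list(A_P = A_P, B_P = B_P, Z = Z, alpha = alpha,
                 sample_ids = colnames(A_P) %||% as.character(seq_len(ncol(A_P)))),
            class = "fused_repr")
}

#' @export
print.fused_repr <- function(x, ...) {
  cat(sprintf("fused representation: %d components x %d samples (alpha = %g)\n",
              nrow(x$Z), ncol(x$Z), x$alpha))
  invisible(x)
}

# Coerce fused_repr or bare matrix to the m x n fused matrix.
fused_matrix <- function(Z) {
  if (inherits(Z, "fused_repr")) Z$Z else as.matrix(Z)
}

#' Project and fuse new data with a fitted sparse CCA
#'
#' Convenience method: z-scores each supplied view, aligns its features
#' to the fit, projects, and (when both views are present) fuses.
#'
#' @param object An [scca] fit.
#' @param view_a,view_b New [omics_view] data; at least one is required.
#' @param alpha Fusion coefficient when both views are given.
#' @param ... Unused.
#' @return A `fused_repr` when both views are supplied, otherwise the
#'   single view's `m x n` variate matrix.
#' @export
predict.scca <- function(object, view_a = NULL, view_b = NULL, alpha = 0.5, ...) {
  prep <- function(v, ids) align_features(zscore_features(v), ids)
  if (!is.null(view_a) && !is.null(view_b)) {
    A_P <- project(object$P_a, prep(view_a, object$feature_ids_a))
    B_P <- project(object$P_b, prep(view_b, object$feature_ids_b))
    fuse(A_P, B_P, alpha)
  } else if (!is.null(view_a)) {
    project(object$P_a, prep(view_a, object$feature_ids_a))
  } else if (!is.null(view_b)) {
    project(object$P_b, prep(view_b, object$feature_ids_b))
  } else stopf("supply view_a, view_b or both")
}
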