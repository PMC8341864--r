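# 2-means cluster index: within-cluster sum of squares about the two
# cluster means divided by the total sum of squares about the grand mean.
cluster_index <- function(X, nstart = 5, iter_max = 50) {
  km <- suppressWarnings(stats::kmeans(X, 2, nstart = nstart, iter.max = iter_max))
  km$tot.withinss / km$totss
}

#' Pairwise cluster-significance tests
#'
#' For every pair of subtypes, tests whether the two clusters could have
#' arisen from a single Gaussian.  The test statistic is the 2-means
#' cluster index CI (within-cluster sum of squares over total sum of
#' squares) computed on the pooled samples of the pair; the null
#' distribution comes from simulated single Gaussians whose sample
#' covariance spectrum is constrained to equal the pair's eigenvalues
#' floored at a background variance, estimated robustly as the squared
#' scaled MAD of all matrix entries (the observed data's deficient axes
#' are raised to the same floor, which keeps observed and null cluster
#' indices exchangeable under the null).  The p-value is the
#' continuity-corrected proportion of null cluster indices at or below
#' the observed one.
#'
#' @param Z A `fused_repr` or `m x n` matrix.
#' @param labels A [label_vector] for the samples of `Z`.
#' @param n_sim Null simulations per pair (>= 100; default 1000).
#' @param seed Integer seed.
#' @param nstart 2-means restarts for each cluster-index evaluation.
#' @return A symmetric k x k matrix of p-values (`NA` diagonal).  Pairs
#'   involving a class with fewer than 3 samples are `NA` with a warning.
#' @export
sigclust_pairwise <- function(Z, labels, n_sim = 1000, seed = 1, nstart = 5) {
  Zm <- fused_matrix(Z)
  labels <- align_labels(labels, colnames(Zm) %||% as.character(seq_len(ncol(Zm))))
  y <- droplevels(labels$labels)
  k <- nlevels(y)
  if (k < 2) stopf("at least 2 classes required")
  if (n_sim < 100) stopf("n_sim must be >= 100")
  P <- matrix(NA_real_, k, k, dimnames = list(levels(y), levels(y)))
  pair_seeds <- derive_seeds(seed, k * (k - 1) / 2)
  s <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    s <- s + 1
    ni <- sum(y == levels(y)[i]); nj <- sum(y == levels(y)[j])
    if (ni < 3 || nj < 3) {
      warnf("pair (%s, %s): a class has fewer than 3 samples; p-value set to NA",
            levels(y)[i], levels(y)[j])
      next
    }
    X <- t(Zm[, y %in% levels(y)[c(i, j)], drop = FALSE])
    P[i, j] <- P[j, i] <- with_seed(pair_seeds[s],
                                    sigclust_one(X, n_sim, nstart))
  }
  P
}

# One SigClust-style test on an n x d sample matrix.
#
# The null is conditioned on the covariance spectrum: the observed data's
# deficient principal axes are raised to the background-variance floor, and
# every simulated Gaussian is recolored so its sample spectrum equals the
# same floored eigenvalues exactly.  Observed and null datasets then share
# identical second-moment structure, so under a single Gaussian the cluster
# indices are exchangeable and the p-value is calibrated; simulating from
# the estimated spectrum without conditioning inherits the sampling
# anisotropy twice and is badly conservative.
sigclust_one <- function(X, n_sim, nstart) {
  n <- nrow(X); d <- ncol(X)
  bg <- stats::mad(as.vector(X))^2          # scaled-MAD background variance
  Xc <- scale(X, scale = FALSE)
  if (d == 1) {
    lam <- max(stats::var(as.vector(Xc)), bg)
    Xf <- Xc * sqrt(lam / max(stats::var(as.vector(Xc)), 1e-12))
    e_vec <- matrix(1, 1, 1)
  } else {
    e <- eigen(stats::cov(X), symmetric = TRUE)
    lam <- pmax(e$values, bg)
    Xf <- Xc %*% e$vectors %*% (sqrt(lam / pmax(e$values, 1e-12)) * t(e$vectors))
  }
  obs <- cluster_index(Xf, nstart)
  s_target <- sqrt((n - 1) * lam)
  null_ci <- vapply(seq_len(n_sim), function(b) {
    Y <- scale(matrix(stats::rnorm(n * d), n, d), scale = FALSE)
    sv <- svd(Y, nu = d, nv = d)
    cluster_index(sv$u %*% (s_target * t(sv$v)), nstart)
  }, numeric(1))
  (1 + sum(null_ci <= obs)) / (n_sim + 1)
}

#' Mean silhouette width of a subtyping
#'
#' Euclidean silhouette in the fused space; singleton classes
#' contribute width 0.  Always in `[-1, 1]`; values near 0 indicate
#' labels unrelated to the geometry.
#'
#' @param Z A `fused_repr` or `m x n` matrix.
#' @param labels A [label_vector] with at least 2 classes.
#' @return The mean silhouette width.
#' @export
silhouette_score <- function(Z, labels) {
  Zm <- fused_matrix(Z)
  labels <- align_labels(labels, colnames(Zm) %||% as.character(seq_len(ncol(Zm))))
  y <- droplevels(labels$labels)
  if (nlevels(y) < 2) stopf("silhouette requires at least 2 classes")
  sil <- cluster::silhouette(as.integer(y), stats::dist(t(Zm)))
  mean(sil[, "sil_width"])
}

#' Association between two subtype taxonomies
#'
#' For every pair of classes across two labelings of the same samples,
#' computes the upper-tail hypergeometric (enrichment) p-value of the
#' observed overlap.  Also reports the McNemar–Bowker symmetry test on
#' the square confusion table obtained after greedily matching classes
#' by maximal overlap — a global test of whether the two taxonomies
#' disagree asymmetrically.
#'
#' @param labels1,labels2 Two [label_vector]s over the same samples.
#' @param p_adjust `"none"` (default) or `"bonferroni"` for the
#'   hypergeometric matrix.
#' @return An object of class `association_matrix`: `p_values` (classes
#'   of `labels1` x classes of `labels2`), `overlap_counts`, and
#'   `bowker` (statistic, df = k(k-1)/2 for k matched classes, p-value,
#'   and the matched class pairs).
#' @export
association_test <- function(labels1, labels2, p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (!setequal(labels1$sample_ids, labels2$sample_ids))
    stopf("the two labelings cover different samples")
  labels2 <- align_labels(labels2, labels1$sample_ids)
  y1 <- droplevels(labels1$labels); y2 <- droplevels(labels2$labels)
  N <- length(y1)
  tab <- table(y1, y2)
  k1 <- nrow(tab); k2 <- ncol(tab)
  pv <- matrix(NA_real_, k1, k2, dimnames = dimnames(tab))
  for (i in seq_len(k1)) for (j in seq_len(k2)) {
    # P(X >= overlap) drawing |class i| samples from N with |class j| marked
    pv[i, j] <- stats::phyper(tab[i, j] - 1, sum(tab[, j]), N - sum(tab[, j]),
                              sum(tab[i, ]), lower.tail = FALSE)
  }
  if (p_adjust == "bonferroni") pv <- pmin(pv * k1 * k2, 1)

  # greedy maximal-overlap matching of classes, then Bowker's symmetry test
  km <- min(k1, k2)
  work <- tab
  pairs <- matrix(NA_integer_, km, 2)
  for (s in seq_len(km)) {
    w <- which(work == max(work), arr.ind = TRUE)[1, ]
    pairs[s, ] <- w
    work[w[1], ] <- -1
    work[, w[2]] <- -1
  }
  S <- tab[pairs[, 1], pairs[, 2], drop = FALSE]
  B <- 0
  if (km >= 2) {
    for (i in seq_len(km - 1)) for (j in seq(i + 1, km)) {
      den <- S[i, j] + S[j, i]
      if (den > 0) B <- B + (S[i, j] - S[j, i])^2 / den
    }
  }
  df <- km * (km - 1) / 2
  bowker_p <- if (df > 0) stats::pchisq(B, df, lower.tail = FALSE) else 1
  structure(list(row_labels = rownames(tab), col_labels = colnames(tab),
                 p_values = pv, overlap_counts = unclass(tab), n = N,
                 bowker = list(statistic = B, df = df, p_value = bowker_p,
                               matched = data.frame(
                                 class1 = rownames(tab)[pairs[, 1]],
                                 class2 = colnames(tab)[pairs[, 2]]))),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association between two taxonomies over %d samples\n", x$n))
  cat("hypergeometric enrichment p-values:\n")
  print(signif(x$p_values, 3))
  cat(sprintf("McNemar-Bowker symmetry: B = %.3f, df = %d, p = %.3g\n",
              x$bowker$statistic, x$bowker$df, x$bowker$p_value))
  invisible(x)
}

#' Log-rank survival test across subtypes
#'
#' k-group log-rank test of equal survival distributions, with
#' per-group Kaplan-Meier step functions exported as tables.
#'
#' @param clinical A [clinical_table].
#' @param labels A [label_vector]; samples are matched by id and must
#'   all carry clinical follow-up.
#' @return An object of class `logrank_test`: `statistic` (chi-square),
#'   `df`, `p_value`, and `km` — one `data.frame(time, n_risk, n_event,
#'   surv)` per group.
#' @export
logrank_by_subtype <- function(clinical, labels) {
  stopifnot(inherits(clinical, "clinical_table"))
  idx <- match(labels$sample_ids, clinical$sample_id)
  if (anyNA(idx)) stopf("%d labeled sample(s) missing from the clinical table", sum(is.na(idx)))
  time <- clinical$time[idx]; event <- clinical$event[idx]
  group <- labels$labels
  sizes <- table(group)
  if (any(sizes == 0)) stopf("empty group(s): %s", paste(names(sizes)[sizes == 0], collapse = ", "))
  if (nlevels(group) < 2) stopf("at least 2 groups required")
  if (sum(event) == 0) stopf("no events observed (all samples censored)")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(droplevels(group)) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(sf$strata) %||% "all", sf$strata %||% length(sf$time))
  km <- split(data.frame(time = sf$time, n_risk = sf$n.risk,
                         n_event = sf$n.event, surv = sf$surv), strata)
  structure(list(statistic = sd$chisq, df = df, p_value = p, km = km),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Correlations between the features selected by a canonical vector pair
#'
#' Identifies the non-zero loadings of one canonical component in both
#' views and computes all pairwise Pearson correlations between the
#' corresponding original expression rows — the interpretability readout
#' of sparse CCA.  A background distribution is built by repeatedly
#' drawing the same numbers of random features from each view and
#' computing the same correlations.
#'
#' @param pair An [scca] fit.
#' @param A,B The [omics_view]s the fit was trained on (original
#'   expression scale is fine; Pearson correlation is scale-free).
#' @param component Which canonical component to interpret (default 1).
#' @param n_background Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return An object of class `variate_correlations`: `observed`
#'   correlations (one per selected mRNA/miRNA pair), the pooled
#'   `background` correlations, the selected feature ids
#'   (`support_a`, `support_b`) and counts.
#' @export
variate_pair_correlations <- function(pair, A, B, component = 1,
                                      n_background = 1000, seed = 1) {
  stopifnot(inherits(pair, "scca"))
  if (component < 1 || component > ncol(pair$P_a))
    stopf("component must lie in 1..%d", ncol(pair$P_a))
  sup_a <- which(pair$P_a[, component] != 0)
  sup_b <- which(pair$P_b[, component] != 0)
  if (!length(sup_a) || !length(sup_b))
    stopf("component %d has an empty support in one view", component)
  ia <- match(pair$feature_ids_a, A$feature_ids)
  ib <- match(pair$feature_ids_b, B$feature_ids)
  if (anyNA(ia) || anyNA(ib)) stopf("views do not carry the fit's features")
  Av <- A$values[ia, , drop = FALSE]; Bv <- B$values[ib, , drop = FALSE]
  observed <- as.vector(stats::cor(t(Av[sup_a, , drop = FALSE]),
                                   t(Bv[sup_b, , drop = FALSE])))
  na <- length(sup_a); nb <- length(sup_b)
  background <- with_seed(seed, {
    unlist(lapply(seq_len(n_background), function(r) {
      ra <- sample(nrow(Av), na)
      rb <- sample(nrow(Bv), nb)
      as.vector(stats::cor(t(Av[ra, , drop = FALSE]), t(Bv[rb, , drop = FALSE])))
    }), use.names = FALSE)
  })
  structure(list(observed = observed, background = background,
                 support_a = pair$feature_ids_a[sup_a],
                 support_b = pair$feature_ids_b[sup_b],
                 n_pairs = na * nb, component = component),
            class = "variate_correlations")
}

#' @export
print.variate_correlations <- function(x, ...) {
  cat(sprintf("canonical component %d: %d non-zero features in view a, %d in view b (%d pairs)\n",
              x$component, length(x$support_a), length(x$support_b), x$n_pairs))
  cat(sprintf("observed |correlation|: mean %.3f; background: mean %.4f (sd %.3f)\n",
              mean(abs(x$observed)), mean(x$background), stats::sd(x$background)))
  invisible(x)
}
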