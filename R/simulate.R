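#' Simulate a two-view cohort with planted sparse canonical structure
#'
#' Generates the statistical structure sparse CCA assumes: every sample
#' carries an `m_latent`-dimensional latent factor whose mean depends on
#' a uniformly drawn subtype, and both views observe the factor through
#' sparse unit-norm loading matrices plus independent Gaussian noise:
#' `A = L_a f + e_a`, `B = L_b f + e_b`.  Each loading column has
#' exactly `support_size` non-zero entries of value
#' `+-1/sqrt(support_size)` at positions drawn without replacement.
#' Subtype means are placed at the vertices of a centered simplex scaled
#' to norm `effect_size` (requires `m_latent >= k_subtypes - 1` for full
#' separation).  Survival times are exponential with per-subtype hazard
#' `baseline_hazard * hazard_ratios[subtype]`; a sample is censored with
#' probability `censor_rate`, in which case the recorded time is uniform
#' on `(0, t)`.
#'
#' The defaults define the reference cohort used throughout the test
#' suite: 300 samples, a 500-feature view and a noisier 120-feature
#' view, four subtypes on three latent factors, and one high-risk
#' subtype (hazard ratio 3).
#'
#' @param n Number of samples.
#' @param D_a,D_b Feature counts of the two views.
#' @param k_subtypes Number of subtypes (>= 2).
#' @param m_latent Number of shared latent factors.
#' @param support_size Non-zero loadings per factor and view.
#' @param effect_size L2 norm of each subtype's latent mean.
#' @param noise_sd_a,noise_sd_b Feature noise standard deviations.
#' @param hazard_ratios Per-subtype hazard multipliers (length
#'   `k_subtypes`).
#' @param censor_rate Expected censoring fraction in `[0, 1)`.
#' @param baseline_hazard Event rate of a hazard-ratio-1 subtype.
#' @param n_confounders Optional count of additional view-specific
#'   latent factors (not shared across views) for robustness studies.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `synthetic_cohort` with elements `mrna` and
#'   `mirna` ([omics_view]s), `clinical` ([clinical_table]) and `truth`
#'   (labels, latent means and factors, loading matrices, noise levels,
#'   hazards, seed).
#' @export
simulate_cohort <- function(n = 300, D_a = 500, D_b = 120, k_subtypes = 4,
                            m_latent = 3, support_size = 10, effect_size = 3,
                            noise_sd_a = 0.5, noise_sd_b = 1.0,
                            hazard_ratios = c(1, 3, 1, 1), censor_rate = 0.2,
                            baseline_hazard = 0.1, n_confounders = 0, seed = 7) {
  if (support_size > min(D_a, D_b))
    stopf("support_size (%d) exceeds the smaller view (%d)", support_size, min(D_a, D_b))
  if (k_subtypes < 2) stopf("k_subtypes must be >= 2")
  if (length(hazard_ratios) != k_subtypes)
    stopf("hazard_ratios must have length k_subtypes")
  if (any(hazard_ratios <= 0)) stopf("hazard ratios must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must lie in [0, 1)")
  if (m_latent < k_subtypes - 1)
    warnf("m_latent < k_subtypes - 1: subtype means cannot be fully separated")

  out <- with_seed(seed, {
    # subtype means: centered simplex vertices, unit norm, scaled
    C <- diag(k_subtypes) - 1 / k_subtypes
    r <- min(m_latent, k_subtypes - 1)
    U <- svd(C)$u[, seq_len(r), drop = FALSE]
    U <- U / sqrt(rowSums(U^2))
    means <- matrix(0, k_subtypes, m_latent)
    means[, seq_len(r)] <- U * effect_size

    subtype <- sample.int(k_subtypes, n, replace = TRUE)
    f <- means[subtype, , drop = FALSE] + matrix(stats::rnorm(n * m_latent), n, m_latent)

    sparse_loadings <- function(D, m) {
      L <- matrix(0, D, m)
      for (j in seq_len(m)) {
        idx <- sample.int(D, support_size)
        L[idx, j] <- sample(c(-1, 1), support_size, replace = TRUE) / sqrt(support_size)
      }
      L
    }
    L_a <- sparse_loadings(D_a, m_latent)
    L_b <- sparse_loadings(D_b, m_latent)
    Am <- L_a %*% t(f) + matrix(stats::rnorm(D_a * n, sd = noise_sd_a), D_a, n)
    Bm <- L_b %*% t(f) + matrix(stats::rnorm(D_b * n, sd = noise_sd_b), D_b, n)
    if (n_confounders > 0) {
      g_a <- matrix(stats::rnorm(n * n_confounders), n, n_confounders)
      g_b <- matrix(stats::rnorm(n * n_confounders), n, n_confounders)
      Am <- Am + sparse_loadings(D_a, n_confounders) %*% t(g_a)
      Bm <- Bm + sparse_loadings(D_b, n_confounders) %*% t(g_b)
    }

    samples <- sprintf("S%03d", seq_len(n))
    dimnames(Am) <- list(sprintf("gene%04d", seq_len(D_a)), samples)
    dimnames(Bm) <- list(sprintf("mir%04d", seq_len(D_b)), samples)

    t_event <- stats::rexp(n, rate = baseline_hazard * hazard_ratios[subtype])
    event <- stats::rbinom(n, 1, 1 - censor_rate)
    time <- ifelse(event == 1, t_event, stats::runif(n, 0, t_event))

    list(mrna = omics_view(Am, view_name = "mrna"),
         mirna = omics_view(Bm, view_name = "mirna"),
         clinical = clinical_table(samples, time, event),
         truth = list(labels = label_vector(samples, paste0("sub", subtype)),
                      latent_means = means, latent_factors = f,
                      loadings_a = L_a, loadings_b = L_b,
                      noise_sd_a = noise_sd_a, noise_sd_b = noise_sd_b,
                      survival_hazards = baseline_hazard * hazard_ratios,
                      seed = seed))
  })
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic two-view cohort: %d samples, %d + %d features, %d subtypes (seed %d)\n",
              ncol(x$mrna$values), nrow(x$mrna$values), nrow(x$mirna$values),
              nlevels(x$truth$labels$labels), x$truth$seed))
  invisible(x)
}

#' Compare a fitted projection and predicted labels with simulated truth
#'
#' Estimated canonical components are matched to planted latent factors
#' by maximal absolute cosine similarity (greedy, sign-invariant); for
#' each matched component the report gives support precision, recall
#' and F1 of the view-a and view-b loadings against the planted
#' non-zero positions, plus the cosine similarity itself.  When
#' predicted labels are supplied, the adjusted Rand index against the
#' planted subtypes is included.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param pair An [scca] fit on that cohort.
#' @param predicted Optional [label_vector] of predicted subtypes.
#' @return A list of class `recovery_report` with a per-component
#'   `components` data frame and optionally `ari`.
#' @export
truth_recovery_report <- function(truth, pair, predicted = NULL) {
  stopifnot(inherits(pair, "scca"))
  m_true <- ncol(truth$loadings_a)
  m_est <- ncol(pair$P_a)
  unit <- function(M) sweep(M, 2, pmax(sqrt(colSums(M^2)), 1e-12), `/`)
  cos_a <- abs(crossprod(unit(truth$loadings_a), unit(pair$P_a)))  # true x est
  rows <- list()
  used_true <- integer(0)
  used_est <- integer(0)
  for (e in seq_len(min(m_est, m_true))) {
    cm <- cos_a
    if (length(used_true)) cm[used_true, ] <- -1
    if (length(used_est)) cm[, used_est] <- -1
    w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    tr <- unname(w[1]); es <- unname(w[2])
    used_true <- c(used_true, tr)
    used_est <- c(used_est, es)
    supp_stats <- function(L_true, P_est) {
      ts <- which(L_true[, tr] != 0); es_ <- which(P_est[, es] != 0)
      tp <- length(intersect(ts, es_))
      prec <- if (length(es_)) tp / length(es_) else 0
      rec <- if (length(ts)) tp / length(ts) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(prec, rec, f1)
    }
    sa <- supp_stats(truth$loadings_a, pair$P_a)
    sb <- supp_stats(truth$loadings_b, pair$P_b)
    rows[[e]] <- data.frame(component = es, factor = tr, cosine_a = cos_a[tr, es],
                            precision_a = sa[1], recall_a = sa[2], f1_a = sa[3],
                            precision_b = sb[1], recall_b = sb[2], f1_b = sb[3])
  }
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  out <- list(components = comp)
  if (!is.null(predicted)) {
    pred <- align_labels(predicted, truth$labels$sample_ids)
    out$ari <- mclust::adjustedRandIndex(as.character(pred$labels),
                                         as.character(truth$labels$labels))
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery against simulated truth:\n")
  print(transform(x$components,
                  cosine_a = round(cosine_a, 3),
                  precision_a = round(precision_a, 3), recall_a = round(recall_a, 3),
                  f1_a = round(f1_a, 3), precision_b = round(precision_b, 3),
                  recall_b = round(recall_b, 3), f1_b = round(f1_b, 3)))
  if (!is.null(x$ari)) cat(sprintf("adjusted Rand index: %.3f\n", x$ari))
  invisible(x)
}
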