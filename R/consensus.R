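#' Consensus clustering of fused samples
#'
#' Resampling-based stability clustering: for each candidate number of
#' clusters `k`, samples are repeatedly subsampled without replacement,
#' clustered with k-means (Euclidean distance, k-means++-style seeding,
#' best of `nstart` restarts), and the fraction of subsamples in which
#' each pair of samples lands in the same cluster is recorded.  The
#' consensus matrix entry (i, j) is the co-clustering count divided by
#' the co-sampling count; final per-k labels come from average-linkage
#' hierarchical clustering of `1 - consensus` cut into `k` groups.
#'
#' @param Z A `fused_repr` from [fuse()] or an `m x n` matrix
#'   (components x samples).
#' @param k_range Candidate cluster numbers, each >= 2.
#' @param n_iter Number of subsampling iterations per k (default 500).
#' @param subsample Subsampling ratio in (0, 1] (default 0.9).
#' @param seed Integer seed; identical seeds give identical results.
#' @param nstart k-means restarts per draw (default 10).
#' @param iter_max k-means iteration cap per restart.
#' @return An object of class `consensus_result`: per-k `consensus`
#'   matrices (symmetric, unit diagonal, entries in `[0, 1]`), per-k
#'   `labels` ([label_vector]s), the area under the consensus-entry CDF
#'   per k (`cdf_area`), its relative change (`delta_area`), `k_range`
#'   and `seed`.  Pairs never co-sampled are set to 0 with a warning.
#' @seealso [select_k()]
#' @export
consensus_cluster <- function(Z, k_range = 2:8, n_iter = 500, subsample = 0.9,
                              seed = 1, nstart = 10, iter_max = 30) {
  Zm <- fused_matrix(Z)
  n <- ncol(Zm)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stopf("all k in k_range must be >= 2")
  if (n < 2 * max(k_range))
    stopf("need at least %d samples for k up to %d", 2 * max(k_range), max(k_range))
  if (!is.numeric(subsample) || subsample <= 0 || subsample > 1)
    stopf("subsample must lie in (0, 1]")
  X <- t(Zm)
  sample_ids <- colnames(Zm) %||% as.character(seq_len(n))
  n_sub <- ceiling(subsample * n)

  res <- with_seed(seed, {
    lapply(k_range, function(k) {
      M <- matrix(0, n, n)  # co-cluster counts
      I <- matrix(0, n, n)  # co-sample counts
      for (it in seq_len(n_iter)) {
        idx <- if (n_sub == n) seq_len(n) else sample(n, n_sub)
        cl <- kmeans_pp(X[idx, , drop = FALSE], k, nstart, iter_max)
        I[idx, idx] <- I[idx, idx] + 1
        for (g in seq_len(k)) {
          s <- idx[cl == g]
          M[s, s] <- M[s, s] + 1
        }
      }
      cons <- matrix(0, n, n)
      seen <- I > 0
      cons[seen] <- M[seen] / I[seen]
      if (!all(seen[upper.tri(seen)]))
        warnf("k = %d: %d sample pair(s) never co-sampled after %d draws; consensus set to 0",
              k, sum(!seen[upper.tri(seen)]), n_iter)
      diag(cons) <- 1
      dimnames(cons) <- list(sample_ids, sample_ids)
      labs <- stats::cutree(stats::hclust(stats::as.dist(1 - cons), method = "average"), k)
      if (length(unique(labs)) < k)
        warnf("k = %d: consensus labels have only %d non-empty classes", k, length(unique(labs)))
      list(consensus = cons, labels = label_vector(sample_ids, labs))
    })
  })
  names(res) <- as.character(k_range)
  # area under the empirical CDF of off-diagonal entries: for values in
  # [0, 1] this is exactly 1 - mean(entries)
  cdf_area <- vapply(res, function(r) {
    v <- r$consensus[upper.tri(r$consensus)]
    1 - mean(v)
  }, numeric(1))
  delta_area <- if (length(cdf_area) == 1) cdf_area else
    c(cdf_area[1], diff(cdf_area) / utils::head(cdf_area, -1))
  names(delta_area) <- names(cdf_area)
  structure(list(k_range = k_range,
                 consensus = lapply(res, `[[`, "consensus"),
                 labels = lapply(res, `[[`, "labels"),
                 cdf_area = cdf_area, delta_area = delta_area, seed = seed,
                 n_iter = n_iter, subsample = subsample),
            class = "consensus_result")
}

# k-means with k-means++-style center seeding drawn from the current RNG
# stream; returns the best-inertia clustering over nstart restarts.
kmeans_pp <- function(X, k, nstart, iter_max) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(nstart)) {
    ctr <- matrix(NA_real_, k, ncol(X))
    ctr[1, ] <- X[sample.int(n, 1), ]
    d2 <- rowSums((X - rep(ctr[1, ], each = n))^2)
    for (j in seq_len(k - 1) + 1) {
      if (all(d2 <= 0)) {
        ctr[j, ] <- X[sample.int(n, 1), ]
      } else {
        ctr[j, ] <- X[sample.int(n, 1, prob = pmax(d2, 0)), ]
      }
      d2 <- pmin(d2, rowSums((X - rep(ctr[j, ], each = n))^2))
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, ctr, iter.max = iter_max)),
      error = function(e) suppressWarnings(stats::kmeans(X, k, iter.max = iter_max)))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering over k = %s (%d iterations, subsample %.2f, seed %d)\n",
              paste(range(x$k_range), collapse = ".."), x$n_iter, x$subsample, x$seed))
  print(data.frame(k = x$k_range, cdf_area = round(x$cdf_area, 4),
                   delta_area = round(x$delta_area, 4), row.names = NULL))
  invisible(x)
}

#' Plot consensus diagnostics
#'
#' Left panel: empirical CDFs of the consensus entries per k.  Right
#' panel: relative change of the area under the CDF, the curve used by
#' [select_k()].
#'
#' @param x A `consensus_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.consensus_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(x$k_range), "Dark 3")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus index", ylab = "CDF",
                 main = "consensus CDF", ...)
  for (i in seq_along(x$k_range)) {
    v <- sort(x$consensus[[i]][upper.tri(x$consensus[[i]])])
    graphics::lines(v, seq_along(v) / length(v), col = cols[i], type = "s")
  }
  graphics::legend("bottomright", legend = paste0("k=", x$k_range),
                   col = cols, lty = 1, cex = 0.8)
  graphics::plot(x$k_range, x$delta_area, type = "b",
                 xlab = "k", ylab = expression(Delta ~ "area"),
                 main = "relative change in CDF area")
  invisible(x)
}

#' Choose the number of clusters from consensus diagnostics
#'
#' The area under the consensus CDF grows as k increases; past the true
#' cluster number the growth flattens.  Among candidate k whose relative
#' area change `delta_area` is at least `min_delta`, this returns the k
#' with the sharpest flattening, i.e. the largest drop ratio
#' `delta(k) / delta(k_next)`.  All diagnostics are attached so the
#' choice can always be overridden manually, which is recommended for
#' borderline data.
#'
#' @param result A `consensus_result`.
#' @param min_delta Minimum relative area change for a k to be a
#'   candidate (default 0.025).
#' @return The selected k (integer) with attributes `delta_area`,
#'   `drop_ratio` and `confidence` (`"ok"` or `"low"` when no dominant
#'   elbow exists, e.g. for unstructured data).  A length-1 `k_range`
#'   returns that k with a warning.
#' @export
select_k <- function(result, min_delta = 0.025) {
  stopifnot(inherits(result, "consensus_result"))
  ks <- result$k_range
  if (length(ks) == 1) {
    warnf("k_range has a single value; returning k = %d", ks)
    return(structure(ks, confidence = "low", delta_area = result$delta_area))
  }
  delta <- pmax(result$delta_area, 1e-8)
  ratio <- delta[-length(delta)] / delta[-1]
  names(ratio) <- names(delta)[-length(delta)]
  cand <- which(result$delta_area[-length(delta)] >= min_delta)
  if (!length(cand)) cand <- 1L
  best <- cand[which.max(ratio[cand])]
  conf <- if (max(ratio[cand]) < 2) "low" else "ok"
  if (conf == "low")
    message("no dominant elbow in the consensus area curve; k selection is low-confidence")
  structure(ks[best], confidence = conf, delta_area = result$delta_area,
            drop_ratio = ratio)
}
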