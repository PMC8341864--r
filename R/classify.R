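#' Train a subtype classifier on the fused representation
#'
#' Fits one of five learners on the columns of the fused matrix (samples
#' in the unified space) against subtype labels.  Defaults follow common
#' practice for expression subtyping: random forest with 1000 trees, SVM
#' with radial kernel and cost 10, 5-nearest neighbours, nearest
#' centroid (minimum distance) and Gaussian naive Bayes.
#'
#' @param Z A `fused_repr` or `m x n` matrix.
#' @param labels A [label_vector] covering the samples of `Z`.
#' @param method One of `"rf"`, `"svm"`, `"knn"`, `"mindis"`, `"nbayes"`.
#' @param params Named list of method-specific overrides: `ntree` (rf),
#'   `cost`/`gamma` (svm), `k` (knn).
#' @param seed Integer seed for learners with internal randomness.
#' @return An object of class `subtype_learner`; combined with an `scca`
#'   fit inside [scca_cc()] it becomes an applicable subtype model.
#' @export
train_classifier <- function(Z, labels, method = c("rf", "svm", "knn", "mindis", "nbayes"),
                             params = list(), seed = 1) {
  method <- match.arg(method)
  Zm <- fused_matrix(Z)
  ids <- colnames(Zm) %||% as.character(seq_len(ncol(Zm)))
  labels <- align_labels(labels, ids)
  y <- droplevels(labels$labels)
  if (nlevels(y) < 2) stopf("training requires at least 2 classes, got %d", nlevels(y))
  sizes <- table(y)
  if (any(sizes < 2))
    stopf("singleton class(es): %s", paste(names(sizes)[sizes < 2], collapse = ", "))
  X <- t(Zm)
  colnames(X) <- rownames(Zm) %||% paste0("CV", seq_len(ncol(X)))
  fitted <- with_seed(seed, switch(method,
    rf = randomForest::randomForest(x = X, y = y,
                                    ntree = params$ntree %||% 1000),
    svm = e1071::svm(x = X, y = y, kernel = "radial",
                     cost = params$cost %||% 10,
                     gamma = params$gamma %||% (1 / ncol(X))),
    knn = list(train = X, cl = y, k = params$k %||% 5),
    mindis = {
      ctr <- t(vapply(levels(y), function(g) colMeans(X[y == g, , drop = FALSE]),
                      numeric(ncol(X))))
      rownames(ctr) <- levels(y)
      ctr
    },
    nbayes = e1071::naiveBayes(x = as.data.frame(X), y = y)))
  structure(list(method = method, params = params, fitted = fitted,
                 class_labels = levels(y), dim = ncol(X), seed = seed),
            class = "subtype_learner")
}

#' @export
print.subtype_learner <- function(x, ...) {
  cat(sprintf("subtype learner '%s' on %d fused dimensions; classes: %s\n",
              x$method, x$dim, paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

# Predict class labels for samples in fused-space coordinates (m x n).
predict_learner <- function(learner, Z) {
  X <- t(fused_matrix(Z))
  colnames(X) <- paste0("CV", seq_len(ncol(X)))
  if (ncol(X) != learner$dim)
    stopf("input has %d dimensions but the learner was trained on %d",
          ncol(X), learner$dim)
  pred <- switch(learner$method,
    rf = as.character(predict(learner$fitted, X)),
    svm = as.character(predict(learner$fitted, X)),
    knn = as.character(class::knn(learner$fitted$train, X, learner$fitted$cl,
                                  k = learner$fitted$k)),
    mindis = {
      ctr <- learner$fitted
      d2 <- outer(rowSums(X^2), rowSums(ctr^2), "+") - 2 * X %*% t(ctr)
      rownames(ctr)[max.col(-d2, ties.method = "first")]
    },
    nbayes = as.character(predict(learner$fitted, as.data.frame(X))))
  factor(pred, levels = learner$class_labels)
}

#' Fit the full multi-omics subtyping model
#'
#' The central fitting function of the package.  Starting from two raw
#' feature-by-sample expression views it (1) z-scores each view and
#' optionally filters low-variability features by MAD, (2) restricts
#' both views to their shared samples, (3) fits a sparse CCA and fuses
#' the projected views with weight `alpha`, (4) discovers subtypes by
#' consensus k-means clustering of the fused samples, selecting the
#' number of clusters by [select_k()] unless `k` is given, and (5)
#' trains a classifier on the fused coordinates against the consensus
#' labels.  The returned model classifies new samples from both views
#' ([predict_fused()]) or from a single view ([predict_single()]).
#'
#' @param mrna,mirna The two [omics_view]s (any two omics types work;
#'   the names reflect the canonical use case).
#' @param penalty_a,penalty_b,n_components,alpha See [scca()] and
#'   [fuse()].
#' @param mad_a,mad_b MAD filter thresholds applied after z-scoring
#'   (0 = no filtering).
#' @param k Number of subtypes; `NULL` (default) selects it from the
#'   consensus diagnostics.
#' @param k_range Candidate cluster numbers when `k` is `NULL`.
#' @param consensus_iter,subsample Consensus clustering controls, see
#'   [consensus_cluster()].
#' @param method,params Classifier choice, see [train_classifier()].
#' @param seed Integer seed governing all randomness.
#' @param preprocess Set to `FALSE` if the views are already z-scored
#'   and filtered.
#' @return An object of class `scca_cc` with elements `scca`, `fused`,
#'   `consensus`, `k`, `labels`, `classifier`, `alpha`, `seed` and
#'   `call`.  Methods: [print.scca_cc()], [summary.scca_cc()],
#'   [predict.scca_cc()], [coef.scca_cc()], [plot.scca_cc()].
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n = 120, D_a = 80, D_b = 40, seed = 1)
#' fit <- scca_cc(coh$mrna, coh$mirna, n_components = 5, k = 4,
#'                consensus_iter = 50, seed = 1)
#' fit
#' }
scca_cc <- function(mrna, mirna, penalty_a = 0.3, penalty_b = 0.3,
                    n_components = NULL, alpha = 0.5, mad_a = 0, mad_b = 0,
                    k = NULL, k_range = 2:8, consensus_iter = 500,
                    subsample = 0.9, method = "rf", params = list(),
                    seed = 1, preprocess = TRUE) {
  cl <- match.call()
  if (preprocess) {
    mrna <- zscore_features(mrna)
    mirna <- zscore_features(mirna)
    if (mad_a > 0) mrna <- mad_filter(mrna, mad_a)
    if (mad_b > 0) mirna <- mad_filter(mirna, mad_b)
  }
  al <- align_samples(mrna, mirna)
  fit <- scca(al$a, al$b, penalty_a = penalty_a, penalty_b = penalty_b,
              n_components = n_components)
  fused <- fuse(project(fit$P_a, al$a), project(fit$P_b, al$b), alpha)
  if (is.null(k)) {
    cons <- consensus_cluster(fused, k_range = k_range, n_iter = consensus_iter,
                              subsample = subsample, seed = seed)
    k <- as.integer(select_k(cons))
  } else {
    cons <- consensus_cluster(fused, k_range = k, n_iter = consensus_iter,
                              subsample = subsample, seed = seed)
    k <- as.integer(k)
  }
  labels <- cons$labels[[as.character(k)]]
  classifier <- train_classifier(fused, labels, method = method,
                                 params = params, seed = seed)
  structure(list(scca = fit, fused = fused, consensus = cons, k = k,
                 labels = labels, classifier = classifier, alpha = alpha,
                 seed = seed, call = cl),
            class = "scca_cc")
}

#' @export
print.scca_cc <- function(x, ...) {
  cat("multi-omics subtype model (sparse CCA fusion)\n")
  cat(sprintf("  views: %s (%d features) / %s (%d features), %d samples\n",
              x$scca$view_names[1], nrow(x$scca$P_a),
              x$scca$view_names[2], nrow(x$scca$P_b), x$scca$n))
  cat(sprintf("  %d canonical components, fusion alpha = %g\n",
              ncol(x$scca$P_a), x$alpha))
  cat(sprintf("  %d subtypes (consensus k-means), classifier: %s\n",
              x$k, x$classifier$method))
  print(table(x$labels$labels))
  invisible(x)
}

#' @export
summary.scca_cc <- function(object, ...) {
  train_pred <- predict_learner(object$classifier, object$fused)
  acc <- mean(as.character(train_pred) == as.character(object$labels$labels))
  sil <- silhouette_score(object$fused, object$labels)
  out <- list(model = object, training_accuracy = acc, silhouette = sil,
              d = object$scca$d,
              support_a = colSums(object$scca$P_a != 0),
              support_b = colSums(object$scca$P_b != 0))
  class(out) <- "summary.scca_cc"
  out
}

#' @export
print.summary.scca_cc <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training accuracy: %.3f; silhouette: %.3f\n",
              x$training_accuracy, x$silhouette))
  cat("  leading canonical values:",
      paste(round(utils::head(x$d, 5), 2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @describeIn scca_cc loading matrix of one view.
coef.scca_cc <- function(object, view = c("a", "b"), ...) {
  coef.scca(object$scca, view)
}

#' @export
#' @describeIn scca_cc consensus diagnostics plot, see
#'   [plot.consensus_result()].
plot.scca_cc <- function(x, ...) plot(x$consensus, ...)

#' Classify new samples from both omics views
#'
#' Each view is z-scored, feature-aligned to the trained projections,
#' projected, and the projections are fused with the model's `alpha`
#' before classification.
#'
#' @param model An [scca_cc] model.
#' @param A_new,B_new New [omics_view]s carrying the same two omics
#'   types the model was trained on.
#' @return A [label_vector] of predicted subtypes.
#' @export
predict_fused <- function(model, A_new, B_new) {
  stopifnot(inherits(model, "scca_cc"))
  fused <- predict.scca(model$scca, view_a = A_new, view_b = B_new,
                        alpha = model$alpha)
  label_vector(fused$sample_ids, predict_learner(model$classifier, fused))
}

#' Classify new samples from a single omics view
#'
#' The view is z-scored, aligned and projected with the corresponding
#' loading matrix; the resulting canonical variates stand in for the
#' fused coordinates.  Because sparse CCA maximizes the correlation of
#' the two projected views, a single projection approximates the fused
#' representation and is fed to the classifier unscaled.
#'
#' @param model An [scca_cc] model.
#' @param X_new A new [omics_view].
#' @param which_view `"a"` if `X_new` is the first (mRNA) view, `"b"`
#'   for the second (miRNA).
#' @return A [label_vector] of predicted subtypes.
#' @export
predict_single <- function(model, X_new, which_view = c("a", "b")) {
  stopifnot(inherits(model, "scca_cc"))
  which_view <- match.arg(which_view)
  Zs <- if (which_view == "a") predict.scca(model$scca, view_a = X_new)
        else predict.scca(model$scca, view_b = X_new)
  label_vector(colnames(Zs), predict_learner(model$classifier, Zs))
}

#' @param object An `scca_cc` model.
#' @param mrna,mirna New data for one or both views.
#' @param ... Unused.
#' @export
#' @describeIn scca_cc dispatches to [predict_fused()] when both views
#'   are supplied and to [predict_single()] otherwise.
predict.scca_cc <- function(object, mrna = NULL, mirna = NULL, ...) {
  if (!is.null(mrna) && !is.null(mirna)) predict_fused(object, mrna, mirna)
  else if (!is.null(mrna)) predict_single(object, mrna, "a")
  else if (!is.null(mirna)) predict_single(object, mirna, "b")
  else stopf("supply mrna, mirna or both")
}

#' Repeated holdout evaluation of fused versus single-view classification
#'
#' Reproduces the repeated train/test design used to compare input
#' types: in each repetition a training subset of samples is drawn, the
#' whole pipeline (z-scoring, sparse CCA, fusion, classifier) is refit
#' on the training samples only, and accuracy against the reference
#' labels is measured on the held-out samples three ways — from the
#' fused representation, from view a alone and from view b alone.
#' Per-method paired Wilcoxon signed-rank tests compare input types
#' across repetitions.
#'
#' @param A,B Raw (unstandardized) sample-aligned [omics_view]s.
#' @param labels Reference [label_vector] for all samples (typically
#'   consensus labels from a full-cohort fit).
#' @param n_train Training samples per repetition (default 200).
#' @param n_reps Number of repetitions (default 100).
#' @param methods Character vector of classifier methods to evaluate.
#' @param penalty_a,penalty_b,n_components,alpha Pipeline settings.
#' @param params Classifier parameter overrides.
#' @param seed Integer seed; a repetition whose training draw misses a
#'   class is redrawn (at most 10 times, then an error).
#' @return An object of class `holdout_report`: `accuracy` is a named
#'   list (per method) of `n_reps x 3` matrices with columns `fused`,
#'   `view_a`, `view_b`; `summary` holds means and standard deviations;
#'   `p_values` the paired Wilcoxon comparisons.
#' @export
repeated_holdout <- function(A, B, labels, n_train = 200, n_reps = 100,
                             methods = "rf", penalty_a = 0.3, penalty_b = 0.3,
                             n_components = NULL, alpha = 0.5,
                             params = list(), seed = 1) {
  al <- align_samples(A, B)
  A <- al$a; B <- al$b
  n <- ncol(A$values)
  if (n_train >= n) stopf("n_train (%d) must be below the sample count (%d)", n_train, n)
  labels <- align_labels(labels, A$sample_ids)
  y <- as.character(labels$labels)
  classes <- unique(y)
  rep_seeds <- derive_seeds(seed, n_reps)
  acc <- lapply(methods, function(m) matrix(NA_real_, n_reps, 3,
    dimnames = list(NULL, c("fused", "view_a", "view_b"))))
  names(acc) <- methods

  for (r in seq_len(n_reps)) {
    res <- with_seed(rep_seeds[r], {
      train <- NULL
      for (try in 1:10) {
        cand <- sample(n, n_train)
        if (all(classes %in% y[cand])) { train <- cand; break }
        message(sprintf("repetition %d: redrawing training set missing a class", r))
      }
      if (is.null(train))
        stopf("repetition %d: could not draw a training set covering every class", r)
      test <- setdiff(seq_len(n), train)
      subv <- function(v, idx) omics_view(v$values[, idx, drop = FALSE],
                                          view_name = v$view_name)
      A_tr <- zscore_features(subv(A, train))
      B_tr <- zscore_features(subv(B, train))
      fit <- scca(A_tr, B_tr, penalty_a = penalty_a, penalty_b = penalty_b,
                  n_components = n_components)
      fused_tr <- fuse(project(fit$P_a, A_tr), project(fit$P_b, B_tr), alpha)
      lab_tr <- label_vector(A_tr$sample_ids, y[train])
      A_te <- subv(A, test); B_te <- subv(B, test)
      truth <- y[test]
      out <- list()
      for (m in methods) {
        model <- structure(list(scca = fit, alpha = alpha,
                                classifier = train_classifier(fused_tr, lab_tr,
                                                              method = m,
                                                              params = params,
                                                              seed = rep_seeds[r])),
                           class = "scca_cc")
        out[[m]] <- c(
          fused = mean(as.character(predict_fused(model, A_te, B_te)$labels) == truth),
          view_a = mean(as.character(predict_single(model, A_te, "a")$labels) == truth),
          view_b = mean(as.character(predict_single(model, B_te, "b")$labels) == truth))
      }
      out
    })
    for (m in methods) acc[[m]][r, ] <- res[[m]]
  }

  summ <- lapply(acc, function(a)
    data.frame(input = colnames(a), mean = colMeans(a),
               sd = apply(a, 2, stats::sd), row.names = NULL))
  pv <- lapply(acc, function(a) {
    pairs <- list(c("fused", "view_a"), c("fused", "view_b"), c("view_a", "view_b"))
    vapply(pairs, function(p) {
      if (n_reps < 2 || all(a[, p[1]] == a[, p[2]])) return(NA_real_)
      suppressWarnings(stats::wilcox.test(a[, p[1]], a[, p[2]],
                                          paired = TRUE)$p.value)
    }, numeric(1)) -> v
    names(v) <- c("fused_vs_a", "fused_vs_b", "a_vs_b")
    v
  })
  structure(list(accuracy = acc, summary = summ, p_values = pv,
                 n_train = n_train, n_reps = n_reps, seed = seed),
            class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("repeated holdout: %d repetitions, %d training samples\n",
              x$n_reps, x$n_train))
  for (m in names(x$summary)) {
    cat(sprintf("method '%s':\n", m))
    s <- x$summary[[m]]
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-7s accuracy %.3f (sd %.3f)\n", s$input[i], s$mean[i], s$sd[i]))
    p <- x$p_values[[m]]
    cat(sprintf("  Wilcoxon signed-rank: fused vs a p=%.2g, fused vs b p=%.2g, a vs b p=%.2g\n",
                p[1], p[2], p[3]))
  }
  invisible(x)
}
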