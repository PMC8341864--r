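#' Construct an omics view
#'
#' An omics view is one feature-by-sample expression matrix with unique
#' feature and sample identifiers.  It is the elementary input of the
#' fusion pipeline: the mRNA view and the miRNA view of a cohort are both
#' `omics_view` objects.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param feature_ids Character vector of unique feature identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @param view_name Label for the view (e.g. `"mrna"`).
#'
#' @return An object of class `omics_view` with elements `values`
#'   (dimnamed matrix), `feature_ids`, `sample_ids` and `view_name`.
#' @export
#' @examples
#' v <- omics_view(matrix(1:6, 3, 2,
#'                        dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' dim(v)
omics_view <- function(values, feature_ids = rownames(values),
                       sample_ids = colnames(values), view_name = "view") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("omics view values must be numeric")
  if (is.null(feature_ids) || is.null(sample_ids))
    stopf("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stopf("%d feature ids for %d rows", length(feature_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stopf("%d sample ids for %d columns", length(sample_ids), ncol(values))
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stopf("duplicated feature ids: %s", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stopf("duplicated sample ids: %s", paste(utils::head(dup, 5), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, view_name = as.character(view_name)),
            class = "omics_view")
}

#' @export
dim.omics_view <- function(x) dim(x$values)

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("omics view '%s': %d features x %d samples\n",
              x$view_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.omics_view <- function(x, ...) x$values

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV matrix with identifiers in the first column and the
#' header row, and returns it in features-by-samples orientation
#' regardless of the orientation on disk.
#'
#' @param path File to read.
#' @param delimiter Field separator, `"\t"` by default.
#' @param orientation Either `"features_in_rows"` (default) or
#'   `"samples_in_rows"`; in the latter case the matrix is transposed
#'   after reading.
#' @param na_action What to do with missing cells: `"error"` (default)
#'   or `"impute_median"` (replace by the feature's median).
#' @param view_name Label for the resulting view; defaults to the file
#'   name without extension.
#'
#' @return An [omics_view].
#' @export
read_omics_matrix <- function(path, delimiter = "\t",
                              orientation = c("features_in_rows", "samples_in_rows"),
                              na_action = c("error", "impute_median"),
                              view_name = NULL) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2) stopf("%s: expected an id column plus data columns", path)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("%s: duplicated row ids: %s", path, paste(utils::head(dup, 5), collapse = ", "))
  body <- tab[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) &
                     !col %in% c("NA", "NaN", "nan", ""))
      if (length(bad))
        stopf("%s: non-numeric value '%s' at row '%s', column '%s'",
              path, col[bad[1]], ids[bad[1]], names(body)[j])
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  if (anyNA(mat)) {
    if (na_action == "error") {
      w <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stopf("%s: missing value at feature '%s', sample '%s' (use na_action = \"impute_median\" to impute)",
            path, rownames(mat)[w[1]], colnames(mat)[w[2]])
    }
    for (i in which(rowSums(is.na(mat)) > 0)) {
      med <- stats::median(mat[i, ], na.rm = TRUE)
      if (is.na(med)) stopf("%s: feature '%s' is entirely missing", path, rownames(mat)[i])
      mat[i, is.na(mat[i, ])] <- med
    }
  }
  if (is.null(view_name))
    view_name <- sub("\\.[^.]*$", "", basename(path))
  omics_view(mat, view_name = view_name)
}

#' Write an omics view to a delimited file
#'
#' Feature identifiers go in the first column (named `feature_id`),
#' sample identifiers in the header.  Round-trips with
#' [read_omics_matrix()].
#'
#' @param view An [omics_view].
#' @param path Output file.
#' @param delimiter Field separator.
#' @export
write_omics_matrix <- function(view, path, delimiter = "\t") {
  df <- data.frame(feature_id = view$feature_ids, view$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score features
#'
#' Centers and scales every feature row to mean 0 and unit sample
#' standard deviation (n - 1 denominator).  Rows with zero variance have
#' no defined z-score and are dropped with a warning.
#'
#' @param view An [omics_view] with at least two samples.
#' @return The standardized [omics_view]; applying the function twice is
#'   a no-op up to floating point error.
#' @export
zscore_features <- function(view) {
  n <- ncol(view$values)
  if (n < 2) stopf("z-scoring requires at least 2 samples, got %d", n)
  m <- rowMeans(view$values)
  centered <- view$values - m
  s <- sqrt(rowSums(centered^2) / (n - 1))
  keep <- is.finite(s) & s > 0
  if (!all(keep)) {
    warnf("dropping %d zero-variance feature(s) from view '%s'",
          sum(!keep), view$view_name)
    if (!any(keep)) stopf("all features have zero variance")
    centered <- centered[keep, , drop = FALSE]
    s <- s[keep]
  }
  omics_view(centered / s, view_name = view$view_name)
}

#' Filter features by median absolute deviation
#'
#' Keeps features whose scaled MAD (`1.4826 * median(|x - median(x)|)`,
#' the normal-consistent estimate used by [stats::mad()]) reaches
#' `threshold`.  At `threshold = 0` only features with MAD exactly zero
#' (constant-median rows) are removed.
#'
#' @param view An [omics_view].
#' @param threshold Non-negative variability cutoff on the z-score scale;
#'   the case studies motivating this package used 0.75 and 0.5.
#' @return The filtered [omics_view], row order preserved.
#' @export
mad_filter <- function(view, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stopf("threshold must be a single non-negative number")
  m <- apply(view$values, 1, stats::mad)
  keep <- if (threshold > 0) m >= threshold else m > 0
  if (!any(keep))
    stopf("MAD filter at threshold %g removed every feature; lower the threshold",
          threshold)
  omics_view(view$values[keep, , drop = FALSE], view_name = view$view_name)
}

#' Restrict two views to their shared samples
#'
#' @param view_a,view_b Two [omics_view] objects.
#' @return A list with elements `a` and `b`: both views restricted to the
#'   intersection of their sample ids, in identical column order.
#' @export
align_samples <- function(view_a, view_b) {
  shared <- intersect(view_a$sample_ids, view_b$sample_ids)
  if (!length(shared))
    stopf("views '%s' and '%s' share no samples", view_a$view_name, view_b$view_name)
  list(a = omics_view(view_a$values[, shared, drop = FALSE], view_name = view_a$view_name),
       b = omics_view(view_b$values[, shared, drop = FALSE], view_name = view_b$view_name))
}

#' Reorder a view's features onto a reference set
#'
#' Used when applying trained projections to an independent dataset whose
#' feature catalogue differs from the training data.  Features absent
#' from `view` become all-zero rows: on the z-score scale zero is the
#' feature mean, the least informative imputation for a projection.
#'
#' @param view An [omics_view] (normally z-scored).
#' @param reference_ids Feature ids the output must have, in order.
#' @return An [omics_view] with exactly `reference_ids` as features.  The
#'   fraction of reference features found is reported via [message()] and
#'   a warning is raised below 50% coverage.
#' @export
align_features <- function(view, reference_ids) {
  reference_ids <- as.character(reference_ids)
  idx <- match(reference_ids, view$feature_ids)
  coverage <- mean(!is.na(idx))
  if (coverage == 0)
    stopf("view '%s' shares no features with the reference", view$view_name)
  out <- matrix(0, length(reference_ids), ncol(view$values),
                dimnames = list(reference_ids, view$sample_ids))
  hit <- !is.na(idx)
  out[hit, ] <- view$values[idx[hit], , drop = FALSE]
  message(sprintf("feature coverage for view '%s': %.3f (%d/%d)",
                  view$view_name, coverage, sum(hit), length(reference_ids)))
  if (coverage < 0.5)
    warnf("feature coverage %.2f below 0.5; projections may be unreliable", coverage)
  omics_view(out, view_name = view$view_name)
}
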