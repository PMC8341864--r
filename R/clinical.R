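#' Construct a clinical table
#'
#' Survival follow-up for a cohort: one row per sample with a
#' non-negative survival time (in whatever unit the study uses) and a
#' 0/1 event indicator (1 = event observed, 0 = censored).  Additional
#' covariate columns are carried along untouched.
#'
#' @param sample_ids Unique sample identifiers.
#' @param time Non-negative survival/censoring times.
#' @param event 0/1 (or logical) event indicators.
#' @param covariates Optional data frame of extra columns.
#' @return A data frame of class `clinical_table` with columns
#'   `sample_id`, `time`, `event` and any covariates.
#' @export
clinical_table <- function(sample_ids, time, event, covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids in clinical table")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stopf("sample_ids, time and event must have equal length")
  if (any(!is.finite(time)) || any(time < 0)) stopf("survival times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0 or 1")
  df <- data.frame(sample_id = sample_ids, time = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from a delimited file
#'
#' The file must contain columns `sample_id`, `time` and `event`; any
#' further columns are kept as covariates.
#'
#' @param path File to read.
#' @param delimiter Field separator.
#' @return A [clinical_table].
#' @export
read_clinical_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("%s: missing required column(s): %s", path,
                          paste(miss, collapse = ", "))
  extra <- tab[, setdiff(names(tab), need), drop = FALSE]
  clinical_table(tab$sample_id, tab$time, tab$event,
                 if (ncol(extra)) extra else NULL)
}

#' Construct a label vector
#'
#' Subtype (or any categorical) assignments for a set of samples.
#'
#' @param sample_ids Unique sample identifiers.
#' @param labels Class assignments, one per sample.
#' @return An object of class `label_vector` with elements `sample_ids`
#'   and `labels` (a factor).
#' @export
label_vector <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids in label vector")
  labels <- if (is.factor(labels)) labels else factor(labels)
  if (length(labels) != length(sample_ids))
    stopf("one label per sample required (%d labels, %d samples)",
          length(labels), length(sample_ids))
  if (nlevels(labels) < 1) stopf("at least one class required")
  structure(list(sample_ids = sample_ids, labels = labels),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("label vector: %d samples, %d classes\n",
              length(x$sample_ids), nlevels(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' @export
length.label_vector <- function(x) length(x$sample_ids)

# Reorder a label vector to the given sample ids (must all be present).
align_labels <- function(labels, sample_ids) {
  idx <- match(sample_ids, labels$sample_ids)
  if (anyNA(idx))
    stopf("%d sample(s) have no label", sum(is.na(idx)))
  label_vector(sample_ids, labels$labels[idx])
}

#' Read subtype labels from a two-column delimited file
#'
#' @param path File with columns `sample_id` and `label` (any second
#'   column name is accepted).
#' @param delimiter Field separator.
#' @return A [label_vector].
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("%s: expected sample_id and label columns", path)
  label_vector(tab[[1]], tab[[2]])
}

#' Write subtype labels to a two-column delimited file
#'
#' @param labels A [label_vector].
#' @param path Output file.
#' @param delimiter Field separator.
#' @export
write_labels <- function(labels, path, delimiter = "\t") {
  utils::write.table(data.frame(sample_id = labels$sample_ids,
                                label = as.character(labels$labels)),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
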