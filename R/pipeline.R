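#' Serialize a fitted subtype model to a directory
#'
#' Writes the loading matrices and canonical values as TSV, the subtype
#' labels as TSV, the configuration (penalties, alpha, classifier
#' method, class labels, seed) as JSON, and the trained learner as an
#' RDS blob.  [read_scca_cc()] restores a model that can classify new
#' data without any access to the training cohort.
#'
#' @param model An [scca_cc] model.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scca_cc <- function(model, dir) {
  stopifnot(inherits(model, "scca_cc"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                             quote = FALSE, row.names = FALSE)
  wtsv(data.frame(feature_id = rownames(model$scca$P_a), model$scca$P_a,
                  check.names = FALSE), "loadings_a.tsv")
  wtsv(data.frame(feature_id = rownames(model$scca$P_b), model$scca$P_b,
                  check.names = FALSE), "loadings_b.tsv")
  wtsv(data.frame(component = colnames(model$scca$P_a), d = model$scca$d),
       "d.tsv")
  if (!is.null(model$labels)) write_labels(model$labels, file.path(dir, "labels.tsv"))
  cfg <- list(package_version = as.character(utils::packageVersion("sccaCC")),
              view_names = model$scca$view_names,
              penalty_a = model$scca$config$penalty_a,
              penalty_b = model$scca$config$penalty_b,
              n_components = model$scca$config$n_components,
              alpha = model$alpha, k = model$k,
              method = model$classifier$method,
              class_labels = model$classifier$class_labels,
              seed = model$seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  saveRDS(model$classifier, file.path(dir, "learner.rds"))
  invisible(dir)
}

#' Load a subtype model from a directory
#'
#' @param dir Directory written by [write_scca_cc()].
#' @return An [scca_cc] model (without the training-cohort fused
#'   representation and consensus matrices).
#' @export
read_scca_cc <- function(dir) {
  rtsv <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                        sep = "\t", check.names = FALSE,
                                        stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  la <- rtsv("loadings_a.tsv"); lb <- rtsv("loadings_b.tsv")
  P_a <- as.matrix(la[, -1, drop = FALSE]); rownames(P_a) <- la[[1]]
  P_b <- as.matrix(lb[, -1, drop = FALSE]); rownames(P_b) <- lb[[1]]
  d <- rtsv("d.tsv")$d
  fit <- structure(list(P_a = P_a, P_b = P_b, d = d,
                        feature_ids_a = rownames(P_a),
                        feature_ids_b = rownames(P_b),
                        view_names = cfg$view_names,
                        config = list(penalty_a = cfg$penalty_a,
                                      penalty_b = cfg$penalty_b,
                                      n_components = cfg$n_components),
                        n = NA_integer_),
                   class = "scca")
  labels <- if (file.exists(file.path(dir, "labels.tsv")))
    read_labels(file.path(dir, "labels.tsv")) else NULL
  structure(list(scca = fit, fused = NULL, consensus = NULL, k = cfg$k,
                 labels = labels,
                 classifier = readRDS(file.path(dir, "learner.rds")),
                 alpha = cfg$alpha, seed = cfg$seed, call = NULL),
            class = "scca_cc")
}

# Default run configuration; see run_pipeline().
default_config <- function() {
  list(mrna = NULL, mirna = NULL, clinical = NULL, delimiter = "\t",
       simulate = NULL, penalty_a = 0.3, penalty_b = 0.3,
       n_components = NULL, alpha = 0.5, mad_a = 0, mad_b = 0,
       k = NULL, k_min = 2, k_max = 8, n_iter = 500, subsample = 0.9,
       method = "rf", seed = 1, out = NULL)
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, holding any subset of the
#' [run_pipeline()] parameters; unspecified fields take their defaults.
#'
#' @param path Configuration file.
#' @return A named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

#' Run the subtyping pipeline end to end
#'
#' Executes preprocess, sparse CCA, fusion, consensus clustering and
#' classifier training in order, writing every intermediate artifact
#' plus a manifest (package version, parameters, seeds, input checksums,
#' per-stage timing) under `config$out`.  Given an identical
#' configuration the run is fully reproducible.  A failing stage aborts
#' with the stage name and leaves a `_PARTIAL` marker naming it.
#'
#' Inputs come either from `config$mrna`/`config$mirna` (paths to
#' delimited matrices) or from `config$simulate` (a named list of
#' [simulate_cohort()] arguments, or the string `"default"`).
#'
#' @param config A named list as produced by [read_run_config()], or a
#'   path to a configuration file.
#' @return The fitted [scca_cc] model, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  out <- config$out
  if (is.null(out)) stopf("config error: 'out' directory is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out, "_PARTIAL")
  timings <- list()
  stage <- function(name, expr) {
    writeLines(name, marker)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    res
  }

  checksums <- list()
  dat <- stage("preprocess", {
    if (!is.null(config$simulate)) {
      args <- if (identical(config$simulate, "default")) list() else config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      coh <- do.call(simulate_cohort, args)
      A <- coh$mrna; B <- coh$mirna
      write_labels(coh$truth$labels, file.path(out, "true_labels.tsv"))
      if (!is.null(coh$clinical))
        utils::write.table(coh$clinical, file.path(out, "clinical.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      if (is.null(config$mrna) || is.null(config$mirna))
        stopf("mrna and mirna paths (or a simulate block) are required")
      for (p in c(config$mrna, config$mirna))
        if (!file.exists(p)) stopf("input file not found: %s", p)
      checksums <<- list(mrna = unname(tools::md5sum(config$mrna)),
                         mirna = unname(tools::md5sum(config$mirna)))
      A <- read_omics_matrix(config$mrna, config$delimiter, view_name = "mrna")
      B <- read_omics_matrix(config$mirna, config$delimiter, view_name = "mirna")
    }
    A <- zscore_features(A); B <- zscore_features(B)
    if (config$mad_a > 0) A <- mad_filter(A, config$mad_a)
    if (config$mad_b > 0) B <- mad_filter(B, config$mad_b)
    al <- align_samples(A, B)
    write_omics_matrix(al$a, file.path(out, "mrna_preprocessed.tsv"))
    write_omics_matrix(al$b, file.path(out, "mirna_preprocessed.tsv"))
    al
  })

  fit <- stage("scca_fit", scca(dat$a, dat$b, penalty_a = config$penalty_a,
                                penalty_b = config$penalty_b,
                                n_components = config$n_components))

  fused <- stage("fuse", {
    fz <- fuse(project(fit$P_a, dat$a), project(fit$P_b, dat$b), config$alpha)
    utils::write.table(data.frame(component = rownames(fz$Z), fz$Z,
                                  check.names = FALSE),
                       file.path(out, "fused.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fz
  })

  consensus <- stage("consensus", {
    krange <- if (!is.null(config$k)) config$k else seq(config$k_min, config$k_max)
    cons <- consensus_cluster(fused, k_range = krange, n_iter = config$n_iter,
                              subsample = config$subsample, seed = config$seed)
    for (kk in names(cons$consensus)) {
      utils::write.table(cons$consensus[[kk]],
                         file.path(out, sprintf("consensus_k%s.tsv", kk)),
                         sep = "\t", quote = FALSE)
      write_labels(cons$labels[[kk]], file.path(out, sprintf("labels_k%s.tsv", kk)))
    }
    jsonlite::write_json(list(k_range = cons$k_range, cdf_area = cons$cdf_area,
                              delta_area = cons$delta_area),
                         file.path(out, "consensus_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    cons
  })

  model <- stage("train", {
    k <- if (!is.null(config$k)) as.integer(config$k)
         else as.integer(select_k(consensus))
    labels <- consensus$labels[[as.character(k)]]
    classifier <- train_classifier(fused, labels, method = config$method,
                                   seed = config$seed)
    m <- structure(list(scca = fit, fused = fused, consensus = consensus,
                        k = k, labels = labels, classifier = classifier,
                        alpha = config$alpha, seed = config$seed, call = NULL),
                   class = "scca_cc")
    write_scca_cc(m, file.path(out, "model"))
    write_labels(labels, file.path(out, "labels.tsv"))
    m
  })

  manifest <- list(package = "sccaCC",
                   version = as.character(utils::packageVersion("sccaCC")),
                   r_version = as.character(getRversion()),
                   stages = names(timings), timings_s = timings,
                   parameters = config[setdiff(names(config), "out")],
                   input_checksums = checksums,
                   selected_k = model$k)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  unlink(marker)
  invisible(model)
}
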