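#' Write a spectral dataset to delimited text
#'
#' Spectra go to a wide CSV whose first column is the wavenumber axis and
#' whose remaining columns (headed by spectrum IDs) are one spectrum each;
#' metadata goes to a companion CSV. Intensities are stored with ten
#' significant digits, so a write/read round trip reproduces values to within
#' 1e-9 relative.
#'
#' @param data Spectral dataset tibble.
#' @param spectra_path,metadata_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, spectra_path, metadata_path) {
  m <- spectra_matrix(data)
  w <- wavenumbers(data)
  wide <- as_tibble(as.data.frame(signif(t(m), 10)), .name_repair = "minimal")
  names(wide) <- data$spectrum_id
  wide <- dplyr::bind_cols(tibble(wavenumber = signif(w, 10)), wide)
  readr::write_csv(wide, spectra_path)
  meta <- data[setdiff(names(data), c("spectra"))]
  readr::write_csv(meta, metadata_path)
  invisible(c(spectra_path, metadata_path))
}

#' Read a spectral dataset from delimited text
#'
#' Validates the schema written by [write_dataset()]: strictly increasing
#' wavenumber column, and a one-to-one match between spectra columns and
#' metadata `spectrum_id` rows. Errors name the offending file and entry.
#'
#' @param spectra_path,metadata_path Input file paths.
#' @return A spectral dataset tibble.
#' @export
read_dataset <- function(spectra_path, metadata_path) {
  for (p in c(spectra_path, metadata_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  wide <- readr::read_csv(spectra_path, show_col_types = FALSE, progress = FALSE)
  if (names(wide)[1] != "wavenumber") {
    abort(sprintf("%s: first column must be `wavenumber`.", spectra_path))
  }
  w <- wide$wavenumber
  if (anyNA(w) || any(diff(w) <= 0)) {
    abort(sprintf("%s: `wavenumber` column must be strictly increasing.", spectra_path))
  }
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  if (!"spectrum_id" %in% names(meta)) {
    abort(sprintf("%s: missing `spectrum_id` column.", metadata_path))
  }
  ids <- names(wide)[-1]
  missing_meta <- setdiff(ids, meta$spectrum_id)
  if (length(missing_meta)) {
    abort(sprintf(
      "%s: no metadata row for spectrum column(s) %s.",
      metadata_path, paste(head(missing_meta, 5), collapse = ", ")
    ))
  }
  missing_spec <- setdiff(meta$spectrum_id, ids)
  if (length(missing_spec)) {
    abort(sprintf(
      "%s: metadata row(s) %s have no spectrum column.",
      spectra_path, paste(head(missing_spec, 5), collapse = ", ")
    ))
  }
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  m <- t(as.matrix(wide[, -1, drop = FALSE]))
  raman_dataset(meta, m, w)
}

#' Read/write basis spectra
#'
#' Basis spectra use the same wide delimited format as datasets, with columns
#' `tissue`, `mixed`, `media`.
#'
#' @param basis Basis dataset (from [make_basis_library()]).
#' @param path File path.
#' @return `write_basis()`: the path, invisibly. `read_basis()`: a basis
#'   dataset tibble.
#' @export
write_basis <- function(basis, path) {
  m <- spectra_matrix(basis)
  wide <- as_tibble(as.data.frame(signif(t(m), 10)), .name_repair = "minimal")
  names(wide) <- basis$basis %||% basis$spectrum_id
  wide <- dplyr::bind_cols(tibble(wavenumber = signif(wavenumbers(basis), 10)), wide)
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(wide)[1] != "wavenumber") {
    abort(sprintf("%s: first column must be `wavenumber`.", path))
  }
  w <- wide$wavenumber
  if (anyNA(w) || any(diff(w) <= 0)) {
    abort(sprintf("%s: `wavenumber` column must be strictly increasing.", path))
  }
  labels <- names(wide)[-1]
  raman_dataset(
    tibble(spectrum_id = labels, basis = labels),
    t(as.matrix(wide[, -1, drop = FALSE])), w
  )
}

#' Read or write a confusion matrix CSV
#'
#' Layout mirrors the printed grading tables: a `true` column of row labels
#' and one column per predicted label.
#'
#' @param cm A `confusion_matrix`.
#' @param path File path.
#' @return `read_confusion_csv()` returns a `confusion_matrix`.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- as.matrix(unclass(cm))
  df <- dplyr::bind_cols(tibble(true = rownames(m)),
                         as_tibble(as.data.frame(m), .name_repair = "minimal"))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "true") abort(sprintf("%s: first column must be `true`.", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$true)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = rownames(m), predicted = colnames(m))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Write/read the ground-truth sidecar of a synthetic dataset
#' @param truth Ground-truth tibble from [simulate_dataset()].
#' @param path JSON file path.
#' @return `read_ground_truth()` returns the tibble (baseline as a matrix
#'   column).
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    spectrum_id = truth$spectrum_id, w_tissue = truth$w_tissue,
    w_mixed = truth$w_mixed, w_media = truth$w_media, grade = truth$grade,
    shift = truth$shift, air_pocket = truth$air_pocket,
    baseline = unname(as.matrix(truth$baseline)),
    wavenumber = as.numeric(colnames(truth$baseline))
  )
  jsonlite::write_json(payload, path, digits = 8, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble(
    spectrum_id = p$spectrum_id, w_tissue = p$w_tissue, w_mixed = p$w_mixed,
    w_media = p$w_media, grade = p$grade, shift = p$shift,
    air_pocket = p$air_pocket
  )
  bl <- as.matrix(p$baseline)
  colnames(bl) <- axis_colnames(p$wavenumber)
  out$baseline <- bl
  out
}

config_schema <- function() {
  list(
    seed = NULL, output_dir = NULL,
    synthetic_data = names(formals(synthetic_config)),
    preprocess = names(formals(preprocess_config)),
    unmixing = c("basis_path", "tissue_min", "media_max", "free_rank"),
    classify = c("response", "binning", "strain", "train_frac", "folds")
  )
}

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML or JSON with a global `seed`, an `output_dir`, and
#' optional `synthetic_data`, `preprocess`, `unmixing`, `classify` sections.
#' Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (e.g. built in code).
#' @export
validate_run_config <- function(cfg) {
  schema <- config_schema()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown_top, collapse = ", ")))
  }
  for (sec in c("synthetic_data", "preprocess", "unmixing", "classify")) {
    if (!is.null(cfg[[sec]])) {
      unknown <- setdiff(names(cfg[[sec]]), schema[[sec]])
      if (length(unknown)) {
        abort(sprintf("Unknown key(s) in `%s`: %s", sec, paste(unknown, collapse = ", ")))
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "ramgrade_output"
  structure(cfg, class = "run_config")
}

# One global seed expands deterministically into per-stage seeds so stages can
# be rerun independently: simulate = seed + 1000, classify split/CV derive
# from seed + 3000 inside run_grading_experiment().
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1000L, classify = 3000L)
  as.integer(seed) + offsets[[stage]]
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate (when a `synthetic_data` section is present) ->
#' preprocess -> unmix/filter -> classify, writing every artifact (dataset,
#' basis, score table with keep flags, retention, confusion matrix,
#' classification-rate report, coefficient map, and a parameter log) into the
#' output directory. Identical configuration and seed give byte-identical
#' reports.
#'
#' @param config A `run_config` (or path to one).
#' @param output_dir Overrides `config$output_dir` when given.
#' @return Invisibly, a list with `report` (the JSON-serializable report) and
#'   `artifacts` (named file paths).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  artifacts <- list()

  # --- data ---------------------------------------------------------------
  syn <- config$synthetic_data %||% list()
  syn$seed <- syn$seed %||% stage_seed(config$seed, "simulate")
  scfg <- do.call(synthetic_config, syn)
  note("simulate: seed=%d, grades=%s, maps/grade=%d", scfg$seed,
       paste(scfg$grade_levels, collapse = ","), scfg$n_maps_per_grade)
  sim <- simulate_dataset(scfg)
  data <- sim$data
  basis <- sim$basis
  artifacts$spectra <- file.path(out_dir, "spectra.csv")
  artifacts$metadata <- file.path(out_dir, "metadata.csv")
  write_dataset(data, artifacts$spectra, artifacts$metadata)
  artifacts$ground_truth <- file.path(out_dir, "ground_truth.json")
  write_ground_truth(sim$truth, artifacts$ground_truth)
  artifacts$basis <- file.path(out_dir, "basis.csv")
  if (!is.null(config$unmixing$basis_path)) {
    basis <- read_basis(config$unmixing$basis_path)
    note("unmix: basis read from %s", config$unmixing$basis_path)
  }
  write_basis(basis, artifacts$basis)
  note("simulate: %d spectra x %d channels", nrow(data), ncol(spectra_matrix(data)))

  # --- preprocess ----------------------------------------------------------
  pcfg <- do.call(preprocess_config, config$preprocess %||% list())
  note("preprocess: sg=%d/%d, baseline=%.0f%%x%d, align %g+/-%g cm-1 x%d",
       pcfg$sg_window, pcfg$sg_order, 100 * pcfg$baseline_window_frac,
       pcfg$baseline_iterations, pcfg$align_center, pcfg$align_halfwidth,
       pcfg$align_passes)
  pre <- preprocess_spectra(data, pcfg)
  artifacts$preprocessed <- file.path(out_dir, "preprocessed_spectra.csv")
  artifacts$preprocessed_metadata <- file.path(out_dir, "preprocessed_metadata.csv")
  write_dataset(pre, artifacts$preprocessed, artifacts$preprocessed_metadata)

  # --- unmix / filter ------------------------------------------------------
  ucfg <- config$unmixing %||% list()
  fit <- fit_gbr_nmf(pre, basis, free_rank = ucfg$free_rank %||% 0)
  filt <- filter_spectra(fit, tissue_min = ucfg$tissue_min %||% 1,
                         media_max = ucfg$media_max %||% 1)
  note("unmix: retention %.1f%% (%d/%d kept)", 100 * filt$retention,
       sum(filt$keep), length(filt$keep))
  score_tbl <- tidy(fit) |>
    tidyr::pivot_wider(names_from = "basis",
                       values_from = c("score", "normalized_score")) |>
    mutate(kept = filt$keep)
  artifacts$scores <- file.path(out_dir, "scores.csv")
  readr::write_csv(score_tbl, artifacts$scores)
  kept <- apply_filter(pre, filt)

  # --- classify ------------------------------------------------------------
  ccfg <- config$classify %||% list()
  scheme <- switch(ccfg$binning %||% "none",
                   none = NULL, lmh = binning_scheme("lmh"),
                   zlmh = binning_scheme("zlmh"),
                   abort("`classify$binning` must be none, lmh or zlmh."))
  report_obj <- run_grading_experiment(
    kept, response = ccfg$response %||% "fibrosis", scheme = scheme,
    strain = ccfg$strain, train_frac = ccfg$train_frac,
    seed = stage_seed(config$seed, "classify"),
    folds = ccfg$folds %||% 10
  )
  note("classify: %s, CR=%.3f on %s (n=%d)", report_obj$response,
       report_obj$cr, report_obj$eval_type, report_obj$n_eval)
  artifacts$confusion <- file.path(out_dir, "confusion_matrix.csv")
  write_confusion_csv(report_obj$confusion, artifacts$confusion)
  artifacts$coefficients <- file.path(out_dir, "coefficient_map.csv")
  readr::write_csv(coefficient_map(report_obj$model), artifacts$coefficients)

  report <- list(
    seed = config$seed,
    retention = filt$retention,
    thresholds = list(tissue_min = filt$tissue_min, media_max = filt$media_max),
    n_spectra = nrow(data), n_kept = sum(filt$keep),
    response = report_obj$response, binning = report_obj$scheme,
    strain = report_obj$strain, eval_type = report_obj$eval_type,
    n_train = report_obj$n_train, n_eval = report_obj$n_eval,
    lambda_min = report_obj$cv$lambda_min, lambda_1se = report_obj$cv$lambda_1se,
    classification_rate = report_obj$cr,
    nonzero_coefficients = sum(report_obj$model$beta != 0)
  )
  artifacts$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, artifacts$report, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  artifacts$log <- file.path(out_dir, "log.txt")
  writeLines(log_lines, artifacts$log)
  invisible(list(report = report, artifacts = artifacts,
                 filter = filt, grading = report_obj))
}
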