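#' Save / load a fitted calibration model
#'
#' Serializes the model together with a format version and its provenance
#' (pretreatment chain, wavelength subset, split, seed) so that a reloaded
#' model is self-contained for prediction. Loading refuses archives written
#' by an incompatible format version.
#'
#' @param model a `nir_model`.
#' @param path file path (`.rds`).
#' @return `save_model()` the path, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nir_model"))
  saveRDS(list(format = 1L,
               package_version = as.character(utils::packageVersion("nircal")),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- readRDS(path)
  if (!is.list(archive) || !identical(archive$format, 1L) ||
      !inherits(archive$model, "nir_model")) {
    rlang::abort("not a compatible nircal model archive.",
                 class = "nircal_format_error")
  }
  archive$model
}

#' Write an experiment bundle's tables to a directory
#'
#' Emits `results.csv` (the comparison table), `predictions.csv`
#' (per-sample measured vs predicted scatter data), `outlier_report.csv`
#' and `manifest.json` (config, seeds, versions).
#'
#' @param bundle a `nir_experiment`.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  stopifnot(inherits(bundle, "nir_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$results, file.path(dir, "results.csv"))
  readr::write_csv(bundle$predictions, file.path(dir, "predictions.csv"))
  readr::write_csv(tibble::as_tibble(bundle$outlier_report),
                   file.path(dir, "outlier_report.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
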