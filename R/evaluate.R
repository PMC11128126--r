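#' Calibration metrics: R2, RMSE, RPD
#'
#' The three standard figures of merit for NIR calibration:
#' `metric_r2` is `1 - SSE/SST`; `metric_rmse` is `sqrt(mean((y - yhat)^2))`
#' (% NR); `metric_rpd` is the ratio of the reference values' sample
#' standard deviation to the RMSEP — RPD > 2 is usable for screening,
#' RPD > 3 indicates good predictive ability.
#'
#' @param y numeric vector of measured values (% NR).
#' @param yhat numeric vector of predictions, same length.
#' @return a single number.
#' @export
metric_r2 <- function(y, yhat) {
  if (length(y) < 2 || length(y) != length(yhat)) {
    rlang::abort("r2 needs two aligned vectors of length >= 2.",
                 class = "nircal_parameter_error")
  }
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-26) {
    rlang::abort("r2 undefined: y has zero variance.", class = "nircal_degenerate_error")
  }
  1 - sum((y - yhat)^2) / sst
}

#' @rdname metric_r2
#' @export
metric_rmse <- function(y, yhat) {
  if (length(y) < 1 || length(y) != length(yhat)) {
    rlang::abort("rmse needs two aligned non-empty vectors.",
                 class = "nircal_parameter_error")
  }
  sqrt(mean((y - yhat)^2))
}

#' @rdname metric_r2
#' @param rmsep prediction RMSE of the model being scored.
#' @param literal if `TRUE`, compute the (dimensionally inconsistent) total
#'   sum of squares over RMSE variant sometimes printed instead of the
#'   standard sd/RMSE ratio. Default `FALSE`.
#' @export
metric_rpd <- function(y, rmsep, literal = FALSE) {
  if (length(y) < 2) {
    rlang::abort("rpd needs >= 2 reference values.", class = "nircal_parameter_error")
  }
  if (rmsep <= 0) {
    rlang::abort("rpd undefined: rmsep must be > 0 (perfect fit sentinel).",
                 class = "nircal_degenerate_error")
  }
  if (literal) sum((y - mean(y))^2) / rmsep else stats::sd(y) / rmsep
}

#' RMSEP restricted to the high-content stratum
#'
#' Breeding work screens for individuals with high rubber content, so models
#' are additionally scored on validation samples with measured content
#' strictly above a cutoff (15% NR by convention).
#'
#' @param y measured validation values (% NR).
#' @param yhat predictions.
#' @param cutoff stratum threshold; samples with `y > cutoff` are scored.
#' @return the stratum RMSE.
#' @export
high_content_rmsep <- function(y, yhat, cutoff = 15) {
  keep <- y > cutoff
  if (!any(keep)) {
    rlang::abort(sprintf("empty high-content stratum (0 samples with y > %g).", cutoff),
                 class = "nircal_stratum_error")
  }
  metric_rmse(y[keep], yhat[keep])
}

#' Cross-validated RMSE for an arbitrary model family
#'
#' Splits the samples into `n_folds` seeded folds, fits the supplied factory
#' on each training complement, pools the out-of-fold predictions and returns
#' their RMSE (plus the CV R2).
#'
#' @param spectra,reference aligned spectra and reference tibbles.
#' @param fit_fun function `(spectra, reference) -> model` whose result
#'   works with [predict()] returning a tibble with a `.pred` column.
#' @param n_folds number of folds, between 2 and n.
#' @param seed integer seed for the fold assignment.
#' @return a one-row tibble: `rmsecv`, `r2cv`, `n`, `n_folds`.
#' @export
rmsecv <- function(spectra, reference, fit_fun, n_folds = 10, seed = 1) {
  check_aligned(spectra, reference)
  n <- nrow(spectra)
  if (n_folds < 2 || n_folds > n) {
    rlang::abort("n_folds must be in [2, n].", class = "nircal_parameter_error")
  }
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  preds <- numeric(n)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    model <- fit_fun(spectra[tr, , drop = FALSE], reference[tr, , drop = FALSE])
    preds[!tr] <- stats::predict(model, spectra[!tr, , drop = FALSE])$.pred
  }
  y <- reference$nr_percent
  tibble::tibble(rmsecv = metric_rmse(y, preds), r2cv = metric_r2(y, preds),
                 n = n, n_folds = n_folds)
}

#' Evaluate a fitted calibration model on a train/validation split
#'
#' @param model a fitted `nir_model`.
#' @param train_spectra,train_reference the (preprocessed, band-selected)
#'   training data the model was fitted on.
#' @param val_spectra,val_reference the matching validation data.
#' @param high_cutoff high-content stratum threshold (% NR); the stratum RMSEP
#'   is `NA` when the stratum is empty.
#' @return a one-row tibble: provenance columns (`family`, `chain`,
#'   `band_method`), `r2_train` (R2c), `rmse_train` (RMSEC), `r2_val` (R2p),
#'   `rmse_val` (RMSEP), `rpd_val` (RPD of the validation set), `high_rmsep`,
#'   `n_train`, `n_val`, `n_high`.
#' @export
evaluate_model <- function(model, train_spectra, train_reference,
                           val_spectra, val_reference, high_cutoff = 15) {
  stopifnot(inherits(model, "nir_model"))
  check_aligned(train_spectra, train_reference)
  check_aligned(val_spectra, val_reference)
  yt <- train_reference$nr_percent
  yv <- val_reference$nr_percent
  pt <- stats::predict(model, train_spectra)$.pred
  pv <- stats::predict(model, val_spectra)$.pred
  rmse_val <- metric_rmse(yv, pv)
  n_high <- sum(yv > high_cutoff)
  tibble::tibble(
    family = model$family,
    chain = model$provenance$chain %||% NA_character_,
    band_method = model$provenance$band_method %||% NA_character_,
    r2_train = metric_r2(yt, pt),
    rmse_train = metric_rmse(yt, pt),
    r2_val = metric_r2(yv, pv),
    rmse_val = rmse_val,
    rpd_val = metric_rpd(yv, rmse_val),
    high_rmsep = if (n_high > 0) high_content_rmsep(yv, pv, high_cutoff) else NA_real_,
    n_train = length(yt), n_val = length(yv), n_high = n_high
  )
}

#' Assemble evaluation rows into a comparison table
#'
#' Binds per-configuration evaluation rows (as produced by
#' [evaluate_model()], optionally with extra provenance columns), sorts by
#' validation RPD and flags the best row overall, mirroring the layout of
#' model-comparison tables in NIR calibration studies.
#'
#' @param results a list of evaluation tibbles or a single bound tibble.
#' @return a tibble sorted by decreasing `rpd_val` with a logical `best`
#'   column.
#' @export
compare_table <- function(results) {
  tab <- if (is.data.frame(results)) tibble::as_tibble(results)
         else dplyr::bind_rows(results)
  if (nrow(tab) == 0) {
    rlang::abort("compare_table needs at least one result.",
                 class = "nircal_parameter_error")
  }
  prov <- intersect(c("sample_form", "family", "chain", "band_method"), names(tab))
  if (anyDuplicated(tab[, prov])) {
    rlang::abort("duplicate provenance rows in comparison table.",
                 class = "nircal_aggregation_error")
  }
  tab <- dplyr::arrange(tab, dplyr::desc(.data$rpd_val),
                        .data$rmse_val)
  tab$best <- seq_len(nrow(tab)) == 1L
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
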