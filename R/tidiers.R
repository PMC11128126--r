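#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a fitted calibration model
#'
#' PLS: one row per wavelength with the regression coefficient at the chosen
#' component count. RF/GBT: one row per wavelength with the engine's variable
#' importance. CNN: one row per epoch of the training-loss curve.
#'
#' @param x a `nir_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.nir_model <- function(x, ...) {
  switch(x$family,
    PLS = tibble::tibble(
      wavelength_nm = as.numeric(x$wl_names),
      coefficient = x$fit$coef_path[, x$fit$ncomp]),
    RF = tibble::tibble(
      wavelength_nm = as.numeric(x$wl_names),
      importance = as.numeric(randomForest::importance(x$fit))),
    GBT = {
      imp <- xgboost::xgb.importance(model = x$fit)
      tibble::tibble(wavelength_nm = as.numeric(imp$Feature),
                     importance = imp$Gain)
    },
    CNN = tibble::tibble(epoch = seq_along(x$fit$loss), loss = x$fit$loss)
  )
}

#' One-row summary of a fitted calibration model
#'
#' @param x a `nir_model`.
#' @param ... unused.
#' @return a one-row tibble with the family, the fitted width and the
#'   family's key hyperparameter.
#' @export
glance.nir_model <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_wavelengths = length(x$wl_names),
    key_hyper = switch(x$family,
      PLS = paste0("components=", x$hyper$n_components),
      RF = paste0("trees=", x$hyper$n_trees),
      GBT = paste0("leaves=", x$hyper$num_leaves, ", lr=", x$hyper$learning_rate),
      CNN = paste0("epochs=", x$hyper$epochs, ", lr=", x$hyper$lr))
  )
}

#' Tidy / summarize an experiment bundle
#'
#' `tidy()` returns the full comparison table; `glance()` the best
#' configuration only.
#'
#' @param x a `nir_experiment`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.nir_experiment <- function(x, ...) x$results

#' @rdname tidy.nir_experiment
#' @export
glance.nir_experiment <- function(x, ...) {
  best <- x$results[x$results$best, ]
  dplyr::select(best, dplyr::any_of(c("sample_form", "family", "chain",
                                      "band_method", "r2_val", "rmse_val",
                                      "rpd_val", "high_rmsep")))
}
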