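#' Plot spectra as wavelength profiles
#'
#' @param spectra a spectra tibble.
#' @param n maximum number of spectra drawn (sampled deterministically from
#'   the head of the set).
#' @param colour_by optional reference tibble; lines are coloured by rubber
#'   content when given.
#' @return a ggplot.
#' @export
plot_spectra <- function(spectra, n = 30, colour_by = NULL) {
  validate_spectra(spectra)
  keep <- spectra[seq_len(min(n, nrow(spectra))), , drop = FALSE]
  long <- tidyr::pivot_longer(keep, -"id", names_to = "wavelength_nm",
                              values_to = "absorbance")
  long$wavelength_nm <- as.numeric(long$wavelength_nm)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                          group = .data$id))
  if (!is.null(colour_by)) {
    long <- dplyr::left_join(long, colour_by, by = "id")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                            group = .data$id,
                                            colour = .data$nr_percent)) +
      ggplot2::scale_colour_viridis_c(name = "NR (%)")
  }
  p + ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nir_outlier_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_err, .data$std_err,
                                       colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "mean_cut"), linetype = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "std_cut"), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "MEAN: mean |prediction error| (% NR)",
                  y = "STD: sd of prediction error (% NR)",
                  colour = "flagged") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nir_cars_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("run", "n_retained", "rmsecv")], -"run",
    names_to = "quantity", values_to = "value")
  best <- object$run[which.min(object$rmsecv)]
  ggplot2::ggplot(long, ggplot2::aes(.data$run, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best, linetype = 3, colour = "firebrick") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Monte-Carlo run",
                  y = NULL,
                  title = "CARS shrinkage and cross-validation trace") +
    ggplot2::theme_minimal()
}

#' Measured-versus-predicted scatter for experiment configurations
#'
#' @param bundle a `nir_experiment`.
#' @param configs optional tibble/data frame with columns `chain`,
#'   `band_method`, `family` restricting the panels; defaults to the best
#'   configuration.
#' @return a ggplot faceted by configuration.
#' @export
plot_predictions <- function(bundle, configs = NULL) {
  stopifnot(inherits(bundle, "nir_experiment"))
  df <- bundle$predictions
  if (is.null(configs)) {
    best <- bundle$results[bundle$results$best, c("chain", "band_method", "family")]
    configs <- best
  }
  df <- dplyr::semi_join(df, configs, by = intersect(names(configs), names(df)))
  df$config <- paste(df$family, df$chain, df$band_method)
  ggplot2::ggplot(df, ggplot2::aes(.data$measured, .data$predicted,
                                   colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~config) +
    ggplot2::labs(x = "measured NR content (%)", y = "predicted NR content (%)") +
    ggplot2::theme_minimal()
}
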