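#' Moving-window smoothing
#'
#' Replaces each point by the mean of a centered window along the wavelength
#' axis (default five points, the usual setting for dried-root spectra). At
#' the spectrum edges the window is truncated to the available points, so the
#' column count is unchanged.
#'
#' @param spectra a spectra tibble.
#' @param window odd window size, >= 3.
#' @return a smoothed spectra tibble.
#' @export
mws <- function(spectra, window = 5) {
  validate_spectra(spectra)
  p <- ncol(spectra) - 1L
  if (window %% 2 == 0 || window < 3 || window > p) {
    rlang::abort("window must be odd, >= 3 and <= the number of wavelengths.",
                 class = "nircal_parameter_error")
  }
  m <- spectra_matrix(spectra)
  h <- (window - 1L) %/% 2L
  # cumulative-sum running mean with truncated edges
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(p) - h, 1L)
  hi <- pmin(seq_len(p) + h, p)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
  as_spectra(out, wavelengths(spectra), ids = spectra$id)
}

#' Standard normal variate
#'
#' Per-spectrum standardization: each row has its own mean subtracted and is
#' divided by its own sample (n-1) standard deviation, removing per-sample
#' multiplicative and additive scatter effects using that spectrum alone.
#'
#' @param spectra a spectra tibble.
#' @return a spectra tibble whose rows have mean 0 and sd 1.
#' @export
snv <- function(spectra) {
  validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv < 1e-14)) {
    bad <- spectra$id[which(sdv < 1e-14)[1]]
    rlang::abort(paste0("degenerate (constant) spectrum: sample ", bad),
                 class = "nircal_degenerate_error")
  }
  as_spectra((m - mu) / sdv, wavelengths(spectra), ids = spectra$id)
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed by ordinary least squares on the reference
#' spectrum, `x = d + m * ref`, and corrected as `(x - d) / m`. The reference
#' must be the column-mean of the *training* spectra; correcting validation
#' data with a reference derived from itself leaks information across the
#' split. With `reference = NULL` the column mean of `spectra` itself is used
#' (appropriate only on a training set).
#'
#' @param spectra a spectra tibble.
#' @param reference numeric vector (one value per wavelength) or NULL.
#' @return a corrected spectra tibble.
#' @export
msc <- function(spectra, reference = NULL) {
  validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  if (is.null(reference)) reference <- colMeans(m)
  if (length(reference) != ncol(m)) {
    rlang::abort("MSC reference length must match the wavelength grid.",
                 class = "nircal_shape_error")
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  slope <- as.numeric(m %*% rc) / denom          # OLS slope on (1, reference)
  offset <- rowMeans(m) - slope * mean(reference)
  if (any(abs(slope) < 1e-12)) {
    rlang::abort("degenerate MSC fit: |slope| < 1e-12.",
                 class = "nircal_degenerate_error")
  }
  as_spectra((m - offset) / slope, wavelengths(spectra), ids = spectra$id)
}

#' First derivative
#'
#' Successive difference along the wavelength axis divided by the grid step
#' (units AU/nm), removing additive baselines. The output has one fewer
#' column; its grid sits at the interval midpoints.
#'
#' @param spectra a spectra tibble on a regular grid with >= 2 wavelengths.
#' @return a derivative spectra tibble.
#' @export
fd <- function(spectra) {
  validate_spectra(spectra)
  wl <- wavelengths(spectra)
  if (length(wl) < 2) {
    rlang::abort("first derivative needs at least 2 wavelengths.",
                 class = "nircal_grid_error")
  }
  step <- grid_step(wl)
  if (is.na(step)) {
    rlang::abort("first derivative needs a regular grid.", class = "nircal_grid_error")
  }
  m <- spectra_matrix(spectra)
  out <- (m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]) / step
  as_spectra(out, (wl[-1] + wl[-length(wl)]) / 2, ids = spectra$id)
}

#' Parse a pretreatment chain specification
#'
#' Chains are written as dash-joined step names as in model tables:
#' `"None"`, `"MWS"`, `"MWS-SNV"`, `"MWS-MSC"`, `"MWS-FD"`, or any other
#' duplicate-free combination of MWS, SNV, MSC, FD. Steps execute
#' left-to-right.
#'
#' @param chain a chain string (case-insensitive) or character vector of steps.
#' @return character vector of steps (length 0 for the identity chain).
#' @export
parse_chain <- function(chain) {
  if (length(chain) == 1 && grepl("-", chain)) {
    chain <- strsplit(chain, "-", fixed = TRUE)[[1]]
  }
  steps <- toupper(trimws(chain))
  steps <- steps[!(steps %in% c("", "NONE"))]
  ok <- c("MWS", "SNV", "MSC", "FD")
  if (!all(steps %in% ok)) {
    rlang::abort(paste0("unknown pretreatment step(s): ",
                        paste(setdiff(steps, ok), collapse = ", ")),
                 class = "nircal_parameter_error")
  }
  if (anyDuplicated(steps)) {
    rlang::abort("chain steps must be duplicate-free.", class = "nircal_parameter_error")
  }
  steps
}

#' Fit a pretreatment chain on training spectra
#'
#' Applies the chain steps in order to the training set and records every
#' train-derived parameter (currently the MSC reference, the column mean of
#' the training spectra at the point MSC executes) so the identical transform
#' can be applied to other data with [apply_chain()].
#'
#' @param train training spectra tibble.
#' @param chain chain string, see [parse_chain()].
#' @param window MWS window size.
#' @return a `nir_chain` object; `$train` holds the processed training set.
#' @export
fit_chain <- function(train, chain = "None", window = 5) {
  steps <- parse_chain(chain)
  validate_spectra(train)
  msc_reference <- NULL
  out <- train
  for (s in steps) {
    if (s == "MSC") {
      msc_reference <- colMeans(spectra_matrix(out))
      out <- msc(out, msc_reference)
    } else {
      out <- switch(s, MWS = mws(out, window), SNV = snv(out), FD = fd(out))
    }
  }
  structure(list(steps = steps, window = window,
                 msc_reference = msc_reference, train = out),
            class = "nir_chain")
}

#' Apply a fitted pretreatment chain to new spectra
#'
#' @param spectra spectra tibble on the same grid the chain was fitted on.
#' @param fit a `nir_chain` from [fit_chain()].
#' @return the processed spectra tibble.
#' @export
apply_chain <- function(spectra, fit) {
  stopifnot(inherits(fit, "nir_chain"))
  validate_spectra(spectra)
  out <- spectra
  for (s in fit$steps) {
    if (s == "MSC") {
      if (is.null(fit$msc_reference)) {
        rlang::abort("chain contains MSC but carries no fitted reference.",
                     class = "nircal_state_error")
      }
      out <- msc(out, fit$msc_reference)
    } else {
      out <- switch(s, MWS = mws(out, fit$window), SNV = snv(out), FD = fd(out))
    }
  }
  out
}

#' @export
print.nir_chain <- function(x, ...) {
  lab <- if (length(x$steps) == 0) "None" else paste(x$steps, collapse = "-")
  cat("<nir_chain> ", lab,
      if ("MSC" %in% x$steps) " (MSC reference fitted)" else "", "\n", sep = "")
  invisible(x)
}

#' The pretreatment chains compared in the study design
#'
#' @return character vector: None, MWS, MWS-SNV, MWS-MSC, MWS-FD.
#' @export
study_chains <- function() c("None", "MWS", "MWS-SNV", "MWS-MSC", "MWS-FD")
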