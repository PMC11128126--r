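new_subset <- function(wl, index, method, extra = list()) {
  res <- tibble::tibble(index = as.integer(index), wavelength_nm = wl)
  structure(res, method = method, extra = extra,
            class = c("nir_subset", class(res)))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength elimination driven by PLS regression-coefficient
#' magnitudes. For each of `n_runs` Monte-Carlo runs: a PLS model is fitted
#' on a random `mc_fraction` of the training samples using the currently
#' retained wavelengths; normalized weights `w_j = |b_j| / sum|b_j|` are
#' taken from its regression vector; an exponentially decreasing function
#' (EDF) forces the retained count down to `ceil(r_i * p)` with
#' `r_i = a * exp(-k * i)` calibrated so run 1 keeps all p wavelengths and
#' run `n_runs` keeps 2; adaptive reweighted sampling (ARS) then draws that
#' many wavelengths with replacement with probabilities `w_j`, keeping the
#' distinct survivors; finally the K-fold RMSECV of a PLS model on the run's
#' retained set is recorded. The subset from the run with minimal RMSECV is
#' returned. `ars = FALSE` replaces the weighted draw by the deterministic
#' top-weight cut.
#'
#' @param spectra,reference aligned *training* data.
#' @param n_runs Monte-Carlo runs (50 is conventional).
#' @param n_components PLS components used throughout.
#' @param n_folds folds for the per-run RMSECV.
#' @param seed RNG seed (subsampling, ARS draws and fold assignment).
#' @param mc_fraction per-run sample fraction.
#' @param ars use adaptive reweighted sampling (default) or a deterministic cut.
#' @return a `nir_subset` (columns `index`, `wavelength_nm`, attributes with
#'   the best run) whose attribute `trace` is a `nir_cars_trace` tibble:
#'   per-run retained counts, RMSECV and the retained-coefficient list.
#' @export
cars_select <- function(spectra, reference, n_runs = 50, n_components = 8,
                        n_folds = 5, seed = 1, mc_fraction = 0.8, ars = TRUE) {
  d <- model_xy(spectra, reference)
  n <- nrow(d$X); p <- ncol(d$X)
  if (p < 2) rlang::abort("CARS needs >= 2 wavelengths.", class = "nircal_parameter_error")
  if (n < 2 * n_folds) {
    rlang::abort("CARS needs n >= 2 * n_folds training samples.",
                 class = "nircal_parameter_error")
  }
  wl <- wavelengths(spectra)
  # EDF constants: run 1 keeps p, run n_runs keeps 2
  k_edf <- log(p / 2) / (n_runs - 1)
  a_edf <- (p / 2)^(1 / (n_runs - 1))
  n_sub <- max(2L, floor(mc_fraction * n))
  res <- withr::with_seed(seed, {
    retained <- seq_len(p)
    runs <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      sub <- sample.int(n, n_sub)
      fit <- pls_core(d$X[sub, retained, drop = FALSE], d$y[sub],
                      min(n_components, length(retained)))
      b <- fit$coef_path[, fit$ncomp]
      w <- abs(b) / sum(abs(b))
      keep_n <- as.integer(min(length(retained), ceiling(a_edf * exp(-k_edf * i) * p)))
      forced <- retained[order(w, decreasing = TRUE)[seq_len(keep_n)]]
      w_forced <- w[match(forced, retained)]
      if (ars) {
        draw <- sample(forced, keep_n, replace = TRUE, prob = w_forced)
        new_ret <- sort(unique(draw))
        if (length(new_ret) < min(2L, keep_n)) {
          # degenerate draw: top up with the highest-weight forced variables
          extra <- forced[order(w_forced, decreasing = TRUE)]
          new_ret <- sort(unique(c(new_ret, extra))[seq_len(2L)])
        }
      } else {
        new_ret <- sort(forced)
      }
      if (length(new_ret) < 2 && i < n_runs) {
        rlang::abort("retained set collapsed below 2 before the final run: shrinkage schedule invalid.",
                     class = "nircal_shrinkage_error")
      }
      coef_kept <- stats::setNames(b[match(new_ret, retained)],
                                   format_wl(wl[new_ret]))
      retained <- new_ret
      cv <- pls_cv_path(d$X[, retained, drop = FALSE], d$y,
                        min(n_components, length(retained)), n_folds,
                        seed = seed + i)
      rmsecv_i <- min(cv$rmsecv)
      if (!is.finite(rmsecv_i)) {
        rlang::abort("non-finite RMSECV in CARS run.", class = "nircal_fit_error")
      }
      runs[[i]] <- list(retained = retained, forced_n = keep_n,
                        rmsecv = rmsecv_i, coef = coef_kept)
    }
    runs
  })
  trace <- tibble::tibble(
    run = seq_len(n_runs),
    n_forced = vapply(res, `[[`, integer(1), "forced_n"),
    n_retained = vapply(res, function(r) length(r$retained), integer(1)),
    rmsecv = vapply(res, `[[`, numeric(1), "rmsecv"),
    coefficients = lapply(res, `[[`, "coef")
  )
  class(trace) <- c("nir_cars_trace", class(trace))
  best <- which.min(trace$rmsecv)
  idx <- res[[best]]$retained
  out <- new_subset(wl[idx], idx, "CARS",
                    extra = list(n_runs = n_runs, best_run = best,
                                 rmsecv_curve = trace$rmsecv))
  attr(out, "trace") <- trace
  out
}

#' The rubber chemical characteristic bands
#'
#' The three NIR windows carrying the C-H overtone/combination absorptions of
#' cis-1,4-polyisoprene: 1100-1250, 1550-1760 and 2100-2400 nm (closed
#' intervals), together spanning 40% of the 850-2500 nm range.
#'
#' `chemical_band_windows()` returns the window table;
#' `chemical_bands()` selects every grid position of a spectra tibble inside
#' them; `band_coverage()` gives the windows' share of a wavelength range in
#' percent.
#'
#' @param spectra a spectra tibble.
#' @return `chemical_bands()`: a `nir_subset`.
#' @export
chemical_bands <- function(spectra) {
  validate_spectra(spectra)
  wl <- wavelengths(spectra)
  win <- chemical_band_windows()
  inside <- vapply(wl, function(l) any(l >= win$lower & l <= win$upper), logical(1))
  if (!any(inside)) {
    rlang::abort("grid does not intersect the chemical characteristic bands.",
                 class = "nircal_band_error")
  }
  new_subset(wl[inside], which(inside), "chemical")
}

#' @rdname chemical_bands
#' @export
chemical_band_windows <- function() chemical_windows_nm()

#' @rdname chemical_bands
#' @param windows a tibble with `lower`, `upper` columns (nm).
#' @param range full wavelength range in nm.
#' @return `band_coverage()`: percent of `range` covered by `windows`.
#' @export
band_coverage <- function(windows = chemical_band_windows(), range = c(850, 2500)) {
  span <- sum(pmin(windows$upper, range[2]) - pmax(windows$lower, range[1]))
  100 * span / (range[2] - range[1])
}

#' Select every wavelength of a spectra tibble
#'
#' @param spectra a spectra tibble.
#' @return a `nir_subset` of method `"full"` covering the whole grid.
#' @export
full_band <- function(spectra) {
  validate_spectra(spectra)
  wl <- wavelengths(spectra)
  new_subset(wl, seq_along(wl), "full")
}

#' Slice a spectra tibble to a wavelength subset
#'
#' Column slice (order preserving) by the subset's wavelengths; the grid is
#' sliced identically, so subsets composed across successive selections keep
#' referring to the original wavelengths.
#'
#' @param spectra a spectra tibble.
#' @param subset a `nir_subset`.
#' @return the sliced spectra tibble.
#' @export
apply_wavelengths <- function(spectra, subset) {
  validate_spectra(spectra)
  cols <- format_wl(subset$wavelength_nm)
  missing <- setdiff(cols, names(spectra)[-1])
  if (length(missing) > 0) {
    rlang::abort(paste0("subset wavelengths absent from the grid: ",
                        paste(utils::head(missing, 3), collapse = ", ")),
                 class = "nircal_bounds_error")
  }
  spectra[, c("id", cols), drop = FALSE]
}

#' @export
print.nir_subset <- function(x, ...) {
  cat("<nir_subset> method:", attr(x, "method"), "|", nrow(x), "wavelengths\n")
  invisible(x)
}

#' Size and share of a wavelength subset
#'
#' @param x a `nir_subset`.
#' @param total total number of wavelengths on the parent grid.
#' @return one-row tibble: `n_selected`, `total`, `fraction_pct`.
#' @export
subset_fraction <- function(x, total) {
  tibble::tibble(n_selected = nrow(x), total = total,
                 fraction_pct = 100 * nrow(x) / total)
}
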