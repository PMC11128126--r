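#' Configuration for the synthetic dried-root NIR generator
#'
#' The generator emulates the statistical structure of diffuse-reflectance
#' spectra of dried rubber-dandelion roots paired with wet-chemistry rubber
#' content: a right-skewed content distribution on \[0, 28.7\]% with an excess
#' of low-content (0-5%) hybrids; analyte absorption confined to the three C-H
#' overtone/combination windows 1100-1250, 1550-1760 and 2100-2400 nm;
#' interfering constituents anywhere on the grid; per-sample additive baseline
#' and multiplicative scatter distortions; iid instrument noise; and an
#' optional minority of grossly corrupted samples.
#'
#' `form = "segment"` models cut root segments, whose rough surface and uneven
#' size raise scatter and noise relative to ground powder (`form = "powder"`).
#'
#' @param n_samples number of samples (the emulated study used 129).
#' @param seed integer RNG seed; with the config it fully determines output.
#' @param form `"powder"` or `"segment"`; presets for scatter/noise level.
#' @param content_mix list: `weight_low` (probability of the low-content
#'   uniform component), `low_range` (% NR), `shape`/`scale` of the gamma
#'   component, `max` truncation (% NR).
#' @param analyte_bands tibble of Gaussian analyte peaks (`center` nm inside
#'   the three chemical windows, `width` = Gaussian sd in nm, `amplitude` in
#'   AU per unit mass fraction).
#' @param n_interferents number of non-analyte constituents with peaks
#'   anywhere on the grid, concentrations independent of the analyte.
#' @param background_amplitude scale of the fixed matrix background spectrum
#'   (broad water/carbohydrate absorption plus a gentle slope, ~1 AU) common
#'   to all samples. Dried plant tissue absorbs strongly everywhere in the
#'   NIR; the analyte is a perturbation on this bulk, which is what makes
#'   per-spectrum normalizations (SNV/MSC) information-preserving.
#' @param baseline list `offset_sd` (AU), `slope_sd` (AU/nm).
#' @param scatter list `mult_sd` (dimensionless), `add_sd` (AU).
#' @param noise_sd iid Gaussian noise sd (AU).
#' @param outlier_fraction fraction of samples corrupted by
#'   [inject_outliers()], in \[0, 0.2\].
#' @param grid wavelength grid in nm; default 850-2498 at 2 nm (825 points).
#' @return a `nir_synth_config` list.
#' @export
synth_config <- function(n_samples = 129,
                         seed = 1L,
                         form = c("powder", "segment"),
                         content_mix = list(weight_low = 0.35,
                                            low_range = c(0, 5),
                                            shape = 5, scale = 3.2,
                                            max = 28.7),
                         analyte_bands = NULL,
                         n_interferents = 3L,
                         background_amplitude = 1,
                         baseline = list(offset_sd = 0.05, slope_sd = 5e-5),
                         scatter = NULL,
                         noise_sd = NULL,
                         outlier_fraction = 0,
                         grid = seq(850, 2498, by = 2)) {
  form <- rlang::arg_match(form)
  if (is.null(analyte_bands)) {
    analyte_bands <- tibble::tibble(
      center = c(1180, 1660, 1720, 2240, 2310),
      width = c(22, 28, 20, 32, 26),
      amplitude = c(0.5, 0.9, 0.7, 1.0, 0.8)
    )
  }
  if (is.null(scatter)) {
    scatter <- if (form == "segment") list(mult_sd = 0.15, add_sd = 0.08)
               else list(mult_sd = 0.08, add_sd = 0.05)
  }
  if (is.null(noise_sd)) noise_sd <- if (form == "segment") 0.008 else 0.003
  cfg <- list(n_samples = as.integer(n_samples), seed = as.integer(seed),
              form = form, content_mix = content_mix,
              analyte_bands = analyte_bands, n_interferents = as.integer(n_interferents),
              background_amplitude = background_amplitude,
              baseline = baseline, scatter = scatter, noise_sd = noise_sd,
              outlier_fraction = outlier_fraction, grid = grid)
  class(cfg) <- "nir_synth_config"
  validate_synth_config(cfg)
}

chemical_windows_nm <- function() {
  tibble::tibble(lower = c(1100, 1550, 2100), upper = c(1250, 1760, 2400))
}

validate_synth_config <- function(cfg) {
  cm <- cfg$content_mix
  if (cm$weight_low < 0 || cm$weight_low > 1) {
    rlang::abort("content_mix$weight_low must be in [0, 1].", class = "nircal_config_error")
  }
  sds <- c(cfg$baseline$offset_sd, cfg$baseline$slope_sd,
           cfg$scatter$mult_sd, cfg$scatter$add_sd, cfg$noise_sd)
  if (any(sds < 0)) {
    rlang::abort("all sd parameters must be >= 0.", class = "nircal_config_error")
  }
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction > 0.2) {
    rlang::abort("outlier_fraction must be in [0, 0.2].", class = "nircal_config_error")
  }
  win <- chemical_windows_nm()
  inside <- vapply(cfg$analyte_bands$center, function(cc) {
    any(cc >= win$lower & cc <= win$upper)
  }, logical(1))
  if (!all(inside)) {
    rlang::abort("every analyte band center must lie inside 1100-1250, 1550-1760 or 2100-2400 nm.",
                 class = "nircal_config_error")
  }
  cfg
}

#' Draw rubber contents from the configured mixture
#'
#' With probability `weight_low` a uniform draw on the low range (0-5% by
#' default, emulating low-rubber hybrids), otherwise a gamma draw truncated to
#' \[0, max\] by inverse-CDF sampling. Defaults are calibrated so that over
#' large n the mean falls near 10.5% and the sd near 7.7% with positive skew.
#'
#' @param cfg a [synth_config()].
#' @return a reference tibble (`id`, `nr_percent`).
#' @export
sample_contents <- function(cfg) {
  stopifnot(inherits(cfg, "nir_synth_config"))
  if (cfg$n_samples < 2) {
    rlang::abort("n_samples must be >= 2.", class = "nircal_config_error")
  }
  cm <- cfg$content_mix
  y <- withr::with_seed(cfg$seed, {
    n <- cfg$n_samples
    pick_low <- stats::runif(n) < cm$weight_low
    low <- stats::runif(n, cm$low_range[1], cm$low_range[2])
    u <- stats::runif(n)
    hi <- stats::qgamma(u * stats::pgamma(cm$max, cm$shape, scale = cm$scale),
                        cm$shape, scale = cm$scale)
    ifelse(pick_low, low, hi)
  })
  tibble::tibble(id = sprintf("S%03d", seq_len(cfg$n_samples)), nr_percent = y)
}

gaussian_peak <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

# fixed dried-tissue matrix background: broad water (1450, 1940 nm) and
# carbohydrate (1200, 2270 nm) absorption on a gently rising baseline
matrix_background <- function(wl, amplitude = 1) {
  amplitude * (0.35 + 2e-4 * (wl - 850) +
                 gaussian_peak(wl, 1200, 80, 0.25) +
                 gaussian_peak(wl, 1450, 90, 0.45) +
                 gaussian_peak(wl, 1940, 110, 0.65) +
                 gaussian_peak(wl, 2270, 180, 0.50))
}

#' Render synthetic absorbance spectra for a reference panel
#'
#' A Beer-Lambert style linear mixture: for sample i with content c_i (% NR),
#' `A_i = bg + (c_i/100) * eps_NR + sum_j z_ij * eps_j + (a_i + b_i * lambda)`,
#' where `bg` is the fixed dried-tissue matrix background,
#' then a per-sample multiplicative/additive scatter distortion
#' `m_i * A_i + d_i` and iid Gaussian noise. `eps_NR` is the sum of the
#' configured analyte peaks; interferent spectra `eps_j` are Gaussian peaks
#' placed anywhere on the grid with concentrations independent of the analyte,
#' so wavelength selection has genuine signal-vs-nuisance structure.
#'
#' @param panel a reference tibble.
#' @param cfg a [synth_config()].
#' @return a spectra tibble aligned to `panel`.
#' @export
render_spectra <- function(panel, cfg) {
  stopifnot(inherits(cfg, "nir_synth_config"))
  validate_reference(panel)
  if (nrow(panel) == 0) {
    rlang::abort("panel must be non-empty.", class = "nircal_config_error")
  }
  wl <- cfg$grid
  n <- nrow(panel)
  p <- length(wl)
  eps_nr <- Reduce(`+`, purrr::pmap(cfg$analyte_bands, function(center, width, amplitude) {
    gaussian_peak(wl, center, width, amplitude)
  }))
  bg <- matrix_background(wl, cfg$background_amplitude)
  m <- withr::with_seed(cfg$seed + 1L, {
    A <- (panel$nr_percent / 100) %o% eps_nr + rep(1, n) %o% bg
    if (cfg$n_interferents > 0) {
      centers <- stats::runif(cfg$n_interferents, min(wl), max(wl))
      widths <- stats::runif(cfg$n_interferents, 20, 60)
      amps <- stats::runif(cfg$n_interferents, 0.3, 1.0)
      eps_int <- vapply(seq_len(cfg$n_interferents), function(j) {
        gaussian_peak(wl, centers[j], widths[j], amps[j])
      }, numeric(p))
      z <- matrix(stats::runif(n * cfg$n_interferents, 0, 0.2), n)
      A <- A + z %*% t(eps_int)
    }
    a <- stats::rnorm(n, 0, cfg$baseline$offset_sd)
    b <- stats::rnorm(n, 0, cfg$baseline$slope_sd)
    A <- A + a %o% rep(1, p) + b %o% wl
    mult <- 1 + stats::rnorm(n, 0, cfg$scatter$mult_sd)
    add <- stats::rnorm(n, 0, cfg$scatter$add_sd)
    A <- A * mult + add
    A + matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n)
  })
  as_spectra(m, wl, ids = panel$id)
}

#' Corrupt a minority of samples with gross outliers
#'
#' Each selected sample is corrupted either by a gross mislabel (its reference
#' value shifted by half the content range, wrapping at the range maximum, so
#' the mismatch is large regardless of the original value) or by a large
#' spectral artifact (a 0.8 AU block over a random 300 nm region). Ground-truth
#' corrupted ids are returned so screening recovery can be scored.
#'
#' @param spectra,panel aligned spectra and reference tibbles.
#' @param cfg a [synth_config()] with `outlier_fraction > 0`.
#' @return list with elements `spectra`, `reference`, `outlier_ids`.
#' @export
inject_outliers <- function(spectra, panel, cfg) {
  stopifnot(inherits(cfg, "nir_synth_config"))
  check_aligned(spectra, panel)
  n <- nrow(panel)
  n_out <- round(cfg$outlier_fraction * n)
  if (cfg$outlier_fraction == 0 || n_out == 0) {
    return(list(spectra = spectra, reference = panel, outlier_ids = character(0)))
  }
  if (cfg$outlier_fraction > 0.2) {
    rlang::abort("outlier_fraction too large.", class = "nircal_config_error")
  }
  res <- withr::with_seed(cfg$seed + 2L, {
    idx <- sample.int(n, n_out)
    kind <- sample(c("label", "spectral"), n_out, replace = TRUE)
    y <- panel$nr_percent
    m <- spectra_matrix(spectra)
    wl <- wavelengths(spectra)
    half <- cfg$content_mix$max / 2
    for (k in seq_len(n_out)) {
      i <- idx[k]
      if (kind[k] == "label") {
        y[i] <- (y[i] + half) %% cfg$content_mix$max
      } else {
        start <- stats::runif(1, min(wl), max(wl) - 300)
        m[i, wl >= start & wl <= start + 300] <-
          m[i, wl >= start & wl <= start + 300] + 0.8
      }
    }
    list(m = m, y = y, idx = idx)
  })
  list(
    spectra = as_spectra(res$m, wavelengths(spectra), ids = spectra$id),
    reference = tibble::tibble(id = panel$id, nr_percent = res$y),
    outlier_ids = sort(panel$id[res$idx])
  )
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: draws contents, renders spectra, and (if configured)
#' injects outliers.
#'
#' @param cfg a [synth_config()].
#' @return list with `spectra`, `reference`, `outlier_ids`.
#' @export
simulate_nir_dataset <- function(cfg = synth_config()) {
  panel <- sample_contents(cfg)
  spectra <- render_spectra(panel, cfg)
  inject_outliers(spectra, panel, cfg)
}
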