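#' Monte-Carlo-subsampling outlier screen
#'
#' Repeatedly fits a fixed-component PLS model on random subsets of the
#' samples and records, for every sample, its prediction errors over the runs
#' in which it was held out. A sample's MEAN (mean absolute held-out error,
#' % NR) and STD (standard deviation of its signed held-out errors) locate it
#' in the MEAN/STD plane; samples beyond either cut line are flagged.
#'
#' The default `"robust"` threshold rule places each cut at
#' `median + 8 * MAD` of the statistic's own distribution (with a 1e-6
#' numerical floor). A rule based on mean and sd suffers from masking: a
#' handful of gross outliers inflates the very statistics the cut is built
#' from, and can push the cut beyond the outliers themselves. The median/MAD
#' fence is insensitive to that contamination; the wide 8-MAD multiplier
#' keeps false flags rare under the heavy-tailed errors typical of
#' raw-spectrum PLS. `rule = "classic"` gives `mean + 3 sd`, and fixed cuts
#' can be supplied to reproduce an externally chosen threshold.
#'
#' @param spectra,reference aligned tibbles (n >= 10 samples).
#' @param n_runs Monte-Carlo runs (>= 50; default 500 so each sample is held
#'   out about 100 times at the default fraction).
#' @param train_fraction fraction fitted per run, in \[0.5, 1).
#' @param n_components fixed PLS component count inside the screen.
#' @param seed RNG seed.
#' @param rule threshold rule, `"robust"` (default) or `"classic"`.
#' @param mean_cut,std_cut optional fixed thresholds overriding the rule.
#' @return a `nir_outlier_report`: tibble with `id`, `mean_err`, `std_err`,
#'   `n_heldout`, `flagged`, plus threshold/run metadata in attributes.
#' @export
mcs_screen <- function(spectra, reference, n_runs = 500, train_fraction = 0.8,
                       n_components = 8, seed = 1,
                       rule = c("robust", "classic"),
                       mean_cut = NULL, std_cut = NULL) {
  rule <- rlang::arg_match(rule)
  d <- model_xy(spectra, reference)
  n <- nrow(d$X)
  if (n < 10) rlang::abort("screen needs n >= 10.", class = "nircal_parameter_error")
  if (train_fraction < 0.5 || train_fraction >= 1) {
    rlang::abort("train_fraction must be in [0.5, 1).", class = "nircal_parameter_error")
  }
  if (n_runs < 50) rlang::abort("n_runs must be >= 50.", class = "nircal_parameter_error")
  n_train <- max(2L, floor(train_fraction * n))
  errs <- withr::with_seed(seed, {
    e <- vector("list", n)
    for (r in seq_len(n_runs)) {
      tr <- sample.int(n, n_train)
      fit <- pls_core(d$X[tr, , drop = FALSE], d$y[tr], n_components)
      held <- setdiff(seq_len(n), tr)
      pred <- pls_core_predict(fit, d$X[held, , drop = FALSE])
      resid <- pred - d$y[held]
      for (j in seq_along(held)) e[[held[j]]] <- c(e[[held[j]]], resid[j])
    }
    e
  })
  n_heldout <- lengths(errs)
  if (any(n_heldout < 2)) {
    rlang::abort("some samples were held out fewer than 2 times; increase n_runs.",
                 class = "nircal_insufficient_runs_error")
  }
  mean_err <- vapply(errs, function(e) mean(abs(e)), numeric(1))
  std_err <- vapply(errs, stats::sd, numeric(1))
  fence <- function(x) {
    if (rule == "robust") stats::median(x) + 8 * stats::mad(x)
    else mean(x) + 3 * stats::sd(x)
  }
  if (is.null(mean_cut)) mean_cut <- max(fence(mean_err), 1e-6)
  if (is.null(std_cut)) std_cut <- max(fence(std_err), 1e-6)
  rep <- tibble::tibble(id = spectra$id, mean_err = mean_err, std_err = std_err,
                        n_heldout = n_heldout,
                        flagged = mean_err > mean_cut | std_err > std_cut)
  structure(rep, mean_cut = mean_cut, std_cut = std_cut, n_runs = n_runs,
            train_fraction = train_fraction, n_components = n_components,
            seed = seed, class = c("nir_outlier_report", class(rep)))
}

#' Drop the samples flagged by an outlier screen
#'
#' @param spectra,reference aligned tibbles the report was computed on.
#' @param report a `nir_outlier_report`.
#' @return list with cleaned `spectra` and `reference` (row order preserved).
#' @export
remove_flagged <- function(spectra, reference, report) {
  check_aligned(spectra, reference)
  if (!identical(spectra$id, report$id)) {
    rlang::abort("report ids do not align with the data.",
                 class = "nircal_alignment_error")
  }
  keep <- !report$flagged
  list(spectra = spectra[keep, , drop = FALSE],
       reference = reference[keep, , drop = FALSE])
}

#' Cross-validated PLS performance before and after outlier removal
#'
#' The accepted justification for deleting screened samples: K-fold RMSECV
#' and CV R2 of a fixed-component PLS model on the full versus the cleaned
#' sample set.
#'
#' @inheritParams remove_flagged
#' @param n_folds CV folds.
#' @param n_components PLS components.
#' @param seed fold-assignment seed.
#' @return a one-row tibble: `rmsecv_before`, `rmsecv_after`, `r2cv_before`,
#'   `r2cv_after`, `n_before`, `n_after`.
#' @export
before_after_cv <- function(spectra, reference, report, n_folds = 10,
                            n_components = 8, seed = 1) {
  check_aligned(spectra, reference)
  if (n_folds > nrow(spectra)) {
    rlang::abort("n_folds must not exceed n.", class = "nircal_parameter_error")
  }
  cleaned <- remove_flagged(spectra, reference, report)
  fit_fun <- function(s, r) fit_pls(s, r, n_components = n_components)
  before <- rmsecv(spectra, reference, fit_fun, n_folds, seed)
  after <- rmsecv(cleaned$spectra, cleaned$reference, fit_fun, n_folds, seed)
  tibble::tibble(rmsecv_before = before$rmsecv, rmsecv_after = after$rmsecv,
                 r2cv_before = before$r2cv, r2cv_after = after$r2cv,
                 n_before = nrow(spectra), n_after = nrow(cleaned$spectra))
}
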