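#' Configure a full calibration experiment
#'
#' Collects every setting of the end-to-end workflow: the data source, the
#' outlier screen, the pretreatment chains, the band-selection methods, the
#' model families and the split ratio, with one master seed from which every
#' stage seed is derived.
#'
#' @param data either a [synth_config()] (data are simulated) or a list with
#'   elements `spectra` and `reference`.
#' @param chains pretreatment chains to run (see [study_chains()]).
#' @param band_methods subset of `"full"`, `"chemical"`, `"cars"`.
#' @param families subset of `"pls"`, `"rf"`, `"gbt"`, `"cnn"`.
#' @param ratio training fraction for the SPXY split.
#' @param seed master seed.
#' @param sample_form label carried into the results table.
#' @param screen list of [mcs_screen()] settings.
#' @param cars list of [cars_select()] settings.
#' @param pls list of [fit_pls()] settings.
#' @param cnn list of [fit_cnn()] settings; grid runs default to 200 epochs,
#'   a desk-scale working size (the full protocol's 20000 remains available).
#' @param high_cutoff high-content stratum threshold (% NR).
#' @return a `nir_run_config` list.
#' @export
run_config <- function(data = synth_config(),
                       chains = study_chains(),
                       band_methods = c("full", "chemical"),
                       families = c("pls", "rf", "gbt", "cnn"),
                       ratio = 0.75,
                       seed = 1,
                       sample_form = NULL,
                       screen = list(),
                       cars = list(),
                       pls = list(),
                       cnn = list(),
                       high_cutoff = 15) {
  band_methods <- match.arg(band_methods, c("full", "chemical", "cars"),
                            several.ok = TRUE)
  families <- match.arg(tolower(families), c("pls", "rf", "gbt", "cnn"),
                        several.ok = TRUE)
  if (length(chains) < 1 || length(band_methods) < 1 || length(families) < 1) {
    rlang::abort("need at least one chain, band method and family.",
                 class = "nircal_config_error")
  }
  if (is.null(sample_form)) {
    sample_form <- if (inherits(data, "nir_synth_config")) data$form else "unknown"
  }
  cfg <- list(
    data = data, chains = chains, band_methods = band_methods,
    families = families, ratio = ratio, seed = as.integer(seed),
    sample_form = sample_form,
    screen = utils::modifyList(list(n_runs = 500, train_fraction = 0.8,
                                    n_components = 8), screen),
    cars = utils::modifyList(list(n_runs = 50, n_components = 8, n_folds = 5),
                             cars),
    pls = utils::modifyList(list(n_components = "auto", n_folds = 10,
                                 max_components = 15), pls),
    cnn = utils::modifyList(list(lr = 0.01, epochs = 200, hidden = 64), cnn),
    high_cutoff = high_cutoff
  )
  class(cfg) <- "nir_run_config"
  cfg
}

fit_family <- function(family, train_s, train_r, cfg, seed, provenance) {
  switch(family,
    pls = fit_pls(train_s, train_r, n_components = cfg$pls$n_components,
                  n_folds = cfg$pls$n_folds,
                  max_components = cfg$pls$max_components,
                  seed = seed, provenance = provenance),
    rf = fit_rf(train_s, train_r, seed = seed, provenance = provenance),
    gbt = fit_gbt(train_s, train_r, seed = seed, provenance = provenance),
    cnn = fit_cnn(train_s, train_r, lr = cfg$cnn$lr, epochs = cfg$cnn$epochs,
                  hidden = cfg$cnn$hidden, seed = seed, provenance = provenance)
  )
}

#' Run the full calibration experiment
#'
#' Executes the workflow end to end: outlier screen on the raw spectra, then
#' per pretreatment chain — SPXY split on the provisionally preprocessed
#' spectra, chain refit on the training rows only (so the MSC reference never
#' sees validation data), per band method a wavelength subset fitted on the
#' training data, and per model family a fit and a stratified evaluation.
#' Everything is deterministic given the config: the manifest records every
#' derived seed.
#'
#' @param cfg a [run_config()].
#' @return a `nir_experiment` list: `results` (the comparison table),
#'   `outlier_report`, `screen_cv` (RMSECV before/after removal), `splits`,
#'   `cars_traces`, `predictions` (per-sample measured vs predicted scatter
#'   data), `manifest`, and the internal provenance used by
#'   [leakage_audit()].
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "nir_run_config"))
  if (inherits(cfg$data, "nir_synth_config")) {
    sim <- simulate_nir_dataset(cfg$data)
    spectra <- sim$spectra; reference <- sim$reference
    truth <- sim$outlier_ids
  } else {
    spectra <- validate_spectra(cfg$data$spectra)
    reference <- validate_reference(cfg$data$reference)
    check_aligned(spectra, reference)
    truth <- NULL
  }
  seed_screen <- cfg$seed + 11L
  report <- mcs_screen(spectra, reference,
                       n_runs = cfg$screen$n_runs,
                       train_fraction = cfg$screen$train_fraction,
                       n_components = cfg$screen$n_components,
                       seed = seed_screen)
  screen_cv <- before_after_cv(spectra, reference, report,
                               n_components = cfg$screen$n_components,
                               seed = seed_screen)
  cleaned <- remove_flagged(spectra, reference, report)
  rows <- list(); preds <- list(); splits <- list()
  cars_traces <- list(); audit <- list()
  for (ci in seq_along(cfg$chains)) {
    chain <- cfg$chains[[ci]]
    provisional <- fit_chain(cleaned$spectra, chain)$train
    split <- spxy_split(provisional, cleaned$reference, cfg$ratio)
    splits[[chain]] <- split
    tr <- apply_split(cleaned$spectra, cleaned$reference, split, "train")
    va <- apply_split(cleaned$spectra, cleaned$reference, split, "validation")
    chain_fit <- fit_chain(tr$spectra, chain)
    train_proc <- chain_fit$train
    val_proc <- apply_chain(va$spectra, chain_fit)
    for (bm in cfg$band_methods) {
      seed_bm <- cfg$seed + 100L * ci + 7L * match(bm, c("full", "chemical", "cars"))
      subset <- switch(bm,
        full = full_band(train_proc),
        chemical = chemical_bands(train_proc),
        cars = cars_select(train_proc, tr$reference,
                           n_runs = cfg$cars$n_runs,
                           n_components = cfg$cars$n_components,
                           n_folds = cfg$cars$n_folds, seed = seed_bm)
      )
      if (bm == "cars") cars_traces[[paste(chain, bm, sep = "|")]] <- attr(subset, "trace")
      tr_s <- apply_wavelengths(train_proc, subset)
      va_s <- apply_wavelengths(val_proc, subset)
      for (fam in cfg$families) {
        provenance <- list(chain = chain, band_method = bm,
                           sample_form = cfg$sample_form, seed = seed_bm)
        model <- fit_family(fam, tr_s, tr$reference, cfg, seed_bm, provenance)
        row <- evaluate_model(model, tr_s, tr$reference, va_s, va$reference,
                              cfg$high_cutoff)
        row$sample_form <- cfg$sample_form
        rows[[length(rows) + 1L]] <- row
        key <- paste(chain, bm, fam, sep = "|")
        preds[[key]] <- dplyr::bind_rows(
          tibble::tibble(sample_form = cfg$sample_form, chain = chain,
                         band_method = bm, family = row$family,
                         id = tr$reference$id, partition = "train",
                         measured = tr$reference$nr_percent,
                         predicted = stats::predict(model, tr_s)$.pred),
          tibble::tibble(sample_form = cfg$sample_form, chain = chain,
                         band_method = bm, family = row$family,
                         id = va$reference$id, partition = "validation",
                         measured = va$reference$nr_percent,
                         predicted = stats::predict(model, va_s)$.pred)
        )
        audit[[key]] <- list(
          chain = chain, band_method = bm, family = row$family,
          msc_reference = chain_fit$msc_reference,
          train_ids = tr$reference$id,
          subset_wl = subset$wavelength_nm,
          cnn_xmean = if (fam == "cnn") model$fit$xmean else NULL
        )
      }
    }
  }
  manifest <- list(
    package = "nircal",
    version = as.character(utils::packageVersion("nircal")),
    r_version = as.character(getRversion()),
    seed = cfg$seed, seed_screen = seed_screen,
    chains = cfg$chains, band_methods = cfg$band_methods,
    families = cfg$families, ratio = cfg$ratio,
    sample_form = cfg$sample_form,
    screen = cfg$screen, cars = cfg$cars, pls = cfg$pls, cnn = cfg$cnn,
    synthetic = inherits(cfg$data, "nir_synth_config")
  )
  structure(list(
    results = compare_table(rows),
    outlier_report = report,
    screen_cv = screen_cv,
    true_outlier_ids = truth,
    splits = splits,
    cars_traces = cars_traces,
    predictions = dplyr::bind_rows(preds),
    manifest = manifest,
    audit = audit,
    cleaned = cleaned,
    config = cfg
  ), class = "nir_experiment")
}

#' @export
print.nir_experiment <- function(x, ...) {
  cat("<nir_experiment>", nrow(x$results), "configurations |",
      sum(x$outlier_report$flagged), "samples screened out\n")
  best <- x$results[x$results$best, ]
  cat(sprintf("  best: %s %s/%s  R2p=%.3f RMSEP=%.3f RPD=%.3f\n",
              best$family, best$chain, best$band_method,
              best$r2_val, best$rmse_val, best$rpd_val))
  invisible(x)
}

#' Audit an experiment bundle for train/validation leakage
#'
#' Recomputes, from the bundle's stored post-screen data, every train-derived
#' statistic each configuration claims to have used — the MSC reference
#' (column mean of the training rows at the point MSC executes), the CNN
#' input standardization means, and the wavelength subsets' provenance — and
#' fails loudly, naming the stage, if any was in fact derived from validation
#' rows.
#'
#' @param bundle a `nir_experiment` from [run_experiment()].
#' @return a tibble (`config`, `stage`, `pass`) on a clean bundle; aborts,
#'   naming the stage, on the first leaky one.
#' @export
leakage_audit <- function(bundle) {
  stopifnot(inherits(bundle, "nir_experiment"))
  rows <- list()
  for (key in names(bundle$audit)) {
    a <- bundle$audit[[key]]
    split <- bundle$splits[[a$chain]]
    tr <- apply_split(bundle$cleaned$spectra, bundle$cleaned$reference,
                      split, "train")
    if (!setequal(a$train_ids, train_ids(split))) {
      rlang::abort(paste0("leakage at split stage for ", key,
                          ": model trained on rows outside the training split."),
                   class = "nircal_leakage_error")
    }
    chain_fit <- fit_chain(tr$spectra, a$chain)
    if (!is.null(a$msc_reference)) {
      if (!isTRUE(all.equal(a$msc_reference, chain_fit$msc_reference,
                            tolerance = 1e-10))) {
        rlang::abort(paste0("leakage at MSC stage for ", key,
                            ": reference is not the training-row column mean."),
                     class = "nircal_leakage_error")
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(config = key, stage = "msc", pass = TRUE)
    }
    if (!is.null(a$cnn_xmean)) {
      train_proc <- chain_fit$train
      cols <- format_wl(a$subset_wl)
      expect <- colMeans(spectra_matrix(train_proc[, c("id", cols)]))
      if (!isTRUE(all.equal(unname(a$cnn_xmean), unname(expect), tolerance = 1e-10))) {
        rlang::abort(paste0("leakage at CNN standardization stage for ", key, "."),
                     class = "nircal_leakage_error")
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(config = key, stage = "cnn_standardize", pass = TRUE)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(config = key, stage = "split", pass = TRUE)
  }
  dplyr::bind_rows(rows)
}
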