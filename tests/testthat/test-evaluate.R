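test_that("R2 matches its definition, worked example included", {
  y <- c(0, 1, 2)
  expect_equal(metric_r2(y, y), 1)
  expect_equal(metric_r2(y, rep(mean(y), 3)), 0)
  expect_equal(metric_r2(y, c(0, 1, 4)), -1)  # 1 - 4/2
  expect_error(metric_r2(rep(2, 5), 1:5), class = "nircal_degenerate_error")

  withr::with_seed(1, {
    yy <- stats::rnorm(50); pp <- yy + stats::rnorm(50, 0, 0.3)
  })
  expect_equal(metric_r2(yy, pp), oracle_r2(yy, pp))
})

test_that("RMSE matches its definition and the loop oracle", {
  expect_equal(metric_rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(metric_rmse(c(0, 0), c(3, -3)), 3)
  withr::with_seed(2, {
    y <- stats::rnorm(40); p <- stats::rnorm(40)
  })
  expect_equal(metric_rmse(y, p), oracle_rmse(y, p))
})

test_that("RPD is the sd/RMSEP ratio with the documented identities", {
  withr::with_seed(3, y <- stats::runif(20, 0, 30))
  s <- stats::sd(y)
  expect_equal(metric_rpd(y, s), 1)
  expect_equal(metric_rpd(y, s / 3), 3)
  expect_equal(metric_rpd(y, s / 2), 2 * metric_rpd(y, s))
  expect_equal(metric_rpd(y, 1.5, literal = TRUE), sum((y - mean(y))^2) / 1.5)
  expect_error(metric_rpd(y, 0), class = "nircal_degenerate_error")

  # rpd^2 = n/(n-1) / (1 - r2) for any paired (y, yhat)
  withr::with_seed(4, yhat <- y + stats::rnorm(20, 0, 2))
  rpd <- metric_rpd(y, metric_rmse(y, yhat))
  expect_equal(rpd^2, 20 / 19 / (1 - metric_r2(y, yhat)))
})

test_that("the high-content stratum error is the RMSE over samples above the cutoff", {
  y <- c(2, 8, 16, 20, 25); yhat <- c(3, 7, 15, 22, 24)
  keep <- y > 15
  expect_equal(high_content_rmsep(y, yhat), oracle_rmse(y[keep], yhat[keep]))
  expect_equal(high_content_rmsep(y, yhat, cutoff = -Inf), metric_rmse(y, yhat))
  expect_equal(high_content_rmsep(y[y > 15], yhat[y > 15], cutoff = 15),
               metric_rmse(y[y > 15], yhat[y > 15]))
  expect_error(high_content_rmsep(c(1, 5), c(1, 5)), class = "nircal_stratum_error")
})

test_that("RMSECV pools out-of-fold predictions; n folds equal an explicit LOO loop", {
  fx <- affine_fixture(n = 20, seed = 5)
  pls2 <- function(s, r) fit_pls(s, r, n_components = 2)
  cv <- rmsecv(fx$spectra, fx$reference, pls2, n_folds = 5, seed = 1)
  expect_lt(cv$rmsecv, 1e-6)

  cfg <- synth_config(n_samples = 15, seed = 6)
  sim <- simulate_nir_dataset(cfg)
  loo <- rmsecv(sim$spectra, sim$reference, pls2, n_folds = 15, seed = 2)
  preds <- vapply(1:15, function(i) {
    m <- pls2(sim$spectra[-i, ], sim$reference[-i, ])
    predict(m, sim$spectra[i, ])$.pred
  }, numeric(1))
  expect_equal(loo$rmsecv, metric_rmse(sim$reference$nr_percent, preds))

  expect_identical(rmsecv(sim$spectra, sim$reference, pls2, n_folds = 5, seed = 9),
                   rmsecv(sim$spectra, sim$reference, pls2, n_folds = 5, seed = 9))
  expect_error(rmsecv(sim$spectra, sim$reference, pls2, n_folds = 30),
               class = "nircal_parameter_error")
})

test_that("comparison tables sort by RPD, flag the best row, and reject duplicates", {
  row <- function(fam, chain, rpd) {
    tibble::tibble(family = fam, chain = chain, band_method = "full",
                   r2_train = .9, rmse_train = 1, r2_val = .9,
                   rmse_val = 1, rpd_val = rpd, high_rmsep = rpd / 2,
                   n_train = 10, n_val = 5, n_high = 2)
  }
  grid <- purrr::map2(rep(c("PLS", "RF", "GBT", "CNN"), each = 5),
                      rep(study_chains(), 4),
                      ~row(.x, .y, stats::runif(1, 1, 6)))
  tab <- compare_table(grid)
  expect_equal(nrow(tab), 20)
  expect_equal(which(tab$best), 1L)
  expect_equal(tab$rpd_val[1], max(tab$rpd_val))
  expect_error(compare_table(c(grid, grid[1])), class = "nircal_aggregation_error")

  single <- compare_table(grid[[1]])
  expect_equal(nrow(single), 1)

  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("evaluate_model assembles the standard report for a fitted model", {
  fx <- planted_fixture(8, n = 60, p = 40, n_planted = 4)
  split <- spxy_split(fx$spectra, fx$reference)
  tr <- nircal:::apply_split(fx$spectra, fx$reference, split, "train")
  va <- nircal:::apply_split(fx$spectra, fx$reference, split, "validation")
  m <- fit_pls(tr$spectra, tr$reference, n_components = 4)
  ev <- evaluate_model(m, tr$spectra, tr$reference, va$spectra, va$reference)
  expect_equal(ev$n_train + ev$n_val, 60)
  expect_lte(ev$r2_val, 1)
  expect_gt(ev$rpd_val, 0)
  expect_equal(ev$rpd_val, stats::sd(va$reference$nr_percent) / ev$rmse_val)
  expect_equal(ev$n_high, sum(va$reference$nr_percent > 15))
})
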