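test_that("PLS at full rank on tall data reproduces the OLS solution", {
  withr::with_seed(1, {
    n <- 40; p <- 6
    X <- matrix(stats::rnorm(n * p), n)
    y <- stats::rnorm(n)
  })
  fit <- nircal:::pls_core(X, y, p)
  ols <- stats::lm.fit(cbind(1, X), y)
  pred_pls <- nircal:::pls_core_predict(fit, X, p)
  pred_ols <- as.numeric(cbind(1, X) %*% ols$coefficients)
  expect_lt(max(abs(pred_pls - pred_ols)), 1e-6)
})

test_that("the first PLS component matches the power-iteration oracle and scores are orthogonal", {
  withr::with_seed(2, {
    X <- matrix(stats::rnorm(50 * 12), 50)
    y <- stats::rnorm(50)
  })
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  # oracle: dominant eigenvector of Xc' yc yc' Xc by power iteration
  M <- crossprod(Xc, yc) %*% t(crossprod(Xc, yc))
  v <- rep(1 / sqrt(12), 12)
  for (i in 1:200) { v <- M %*% v; v <- v / sqrt(sum(v^2)) }
  fit <- nircal:::pls_core(X, y, 4)
  w1 <- fit$W[, 1]
  expect_lt(min(sum((w1 - v)^2), sum((w1 + v)^2)), 1e-10)

  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("PLS agrees with an independent NIPALS implementation", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(40 * 30), 40,
                dimnames = list(NULL, paste0("w", 1:30)))
    y <- stats::rnorm(40)
  })
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pm <- as.numeric(predict(mo, X)$predict[, , 3])
  ours <- nircal:::pls_core(X, y, 3)
  expect_lt(max(abs(pm - nircal:::pls_core_predict(ours, X, 3))), 1e-6)
})

test_that("automatic component selection minimizes the cross-validated error path", {
  fx <- planted_fixture(4, n = 50, p = 30, n_planted = 4)
  m <- fit_pls(fx$spectra, fx$reference, n_components = "auto", n_folds = 5, seed = 2)
  path <- m$hyper$rmsecv_path
  expect_true(m$hyper$n_components >= 1 && m$hyper$n_components <= 15)
  expect_equal(path[m$hyper$n_components], min(path))
  # oracle: per-count CV with the same folds reproduces the path
  d <- nircal:::model_xy(fx$spectra, fx$reference)
  again <- nircal:::pls_cv_path(d$X, d$y, length(path), 5, seed = 2)$rmsecv
  expect_equal(path, again)
  expect_error(fit_pls(as_spectra(matrix(1, 5, 3), c(1000, 1002, 1004)),
                       tibble::tibble(id = sprintf("S%03d", 1:5), nr_percent = 1:5),
                       n_components = 2),
               class = "nircal_fit_error")
})

test_that("tree ensembles honor constant targets, seeds, and the training range", {
  sp <- tiny_spectra(20, 15, seed = 5)
  const <- tibble::tibble(id = sp$id, nr_percent = rep(7, 20))
  for (f in list(fit_rf, fit_gbt)) {
    m <- suppressWarnings(f(sp, const, seed = 1)) # randomForest warns on constant y
    expect_true(all(abs(predict(m, sp)$.pred - 7) < 1e-6))
  }
  ref <- tibble::tibble(id = sp$id, nr_percent = withr::with_seed(5, stats::runif(20, 0, 30)))
  m1 <- fit_rf(sp, ref, seed = 3); m2 <- fit_rf(sp, ref, seed = 3)
  expect_equal(predict(m1, sp), predict(m2, sp))
  g1 <- fit_gbt(sp, ref, seed = 3); g2 <- fit_gbt(sp, ref, seed = 3)
  expect_equal(predict(g1, sp), predict(g2, sp))

  # tree means never extrapolate beyond the training target range
  probe <- as_spectra(spectra_matrix(sp) * 3 + 1, wavelengths(sp))
  for (m in list(m1, g1)) {
    p <- predict(m, probe)$.pred
    expect_true(all(p >= min(ref$nr_percent) - 1e-9))
    expect_true(all(p <= max(ref$nr_percent) + 1e-9))
  }
})

test_that("boosting training error is non-increasing in rounds and RF beats PLS on a step response", {
  withr::with_seed(6, {
    n <- 60; p <- 20
    X <- matrix(stats::rnorm(n * p), n)
    y <- ifelse(X[, 3] > 0, 20, 5) + stats::rnorm(n, 0, 0.5)
  })
  sp <- as_spectra(X, seq(1000, by = 2, length.out = p))
  ref <- tibble::tibble(id = sp$id, nr_percent = y)
  e1 <- metric_rmse(y, predict(fit_gbt(sp, ref, n_rounds = 1, seed = 1), sp)$.pred)
  e100 <- metric_rmse(y, predict(fit_gbt(sp, ref, n_rounds = 100, seed = 1), sp)$.pred)
  expect_lte(e100, e1)

  split <- spxy_split(sp, ref, ratio = 0.7)
  tr <- nircal:::apply_split(sp, ref, split, "train")
  va <- nircal:::apply_split(sp, ref, split, "validation")
  r2 <- function(m) metric_r2(va$reference$nr_percent, predict(m, va$spectra)$.pred)
  expect_gte(r2(fit_rf(tr$spectra, tr$reference, seed = 1)),
             r2(fit_pls(tr$spectra, tr$reference, n_folds = 5)))
})

test_that("leaf-wise boosting predicts the sparse high-content stratum at least as well as RF", {
  # skewed content with few high samples and noisier low-content spectra,
  # mirroring the breeding-screen setting; majority over 10 seeds
  wins <- 0; tried <- 0
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- 120; p <- 50
      y <- c(stats::runif(48, 0, 5), 28.7 * stats::rbeta(72, 2, 3))
      X <- matrix(stats::rnorm(n * p, 0, 0.25), n)
      X[, 1:5] <- X[, 1:5] + y %o% c(1, .8, .6, .4, .2) / 10
      X <- X + matrix(stats::rnorm(n * p, 0, 0.25), n) * (y < 12)
    })
    sp <- as_spectra(X, seq(1000, by = 2, length.out = p))
    ref <- tibble::tibble(id = sp$id, nr_percent = y)
    split <- spxy_split(sp, ref)
    tr <- nircal:::apply_split(sp, ref, split, "train")
    va <- nircal:::apply_split(sp, ref, split, "validation")
    if (sum(va$reference$nr_percent > 15) < 2) next
    tried <- tried + 1
    hg <- high_content_rmsep(va$reference$nr_percent,
                             predict(fit_gbt(tr$spectra, tr$reference, seed = s), va$spectra)$.pred)
    hr <- high_content_rmsep(va$reference$nr_percent,
                             predict(fit_rf(tr$spectra, tr$reference, seed = s), va$spectra)$.pred)
    wins <- wins + (hg <= hr)
  }
  expect_gt(wins / tried, 0.5)
})

test_that("the 1-D CNN has the stated architecture arithmetic and trains deterministically", {
  expect_equal(nircal:::cnn_dims(825)$l1, 81)  # floor((825-20)/10)+1
  expect_equal(nircal:::cnn_dims(825)$l2, 79)
  expect_error(nircal:::cnn_dims(19), class = "nircal_architecture_error")

  fx <- planted_fixture(7, n = 25, p = 60, n_planted = 5,
                        beta_range = c(0.5, 1), noise_sd = 0.2)
  m1 <- fit_cnn(fx$spectra, fx$reference, epochs = 50, seed = 2)
  expect_true(all(diff(m1$fit$loss[1:10]) < 0))  # monotone early descent
  m2 <- fit_cnn(fx$spectra, fx$reference, epochs = 50, seed = 2)
  expect_equal(m1$fit$par, m2$fit$par, tolerance = 1e-12)
  expect_equal(predict(m1, fx$spectra), predict(m2, fx$spectra))

  # full-batch training is invariant to sample order
  perm <- withr::with_seed(1, sample(25))
  m3 <- fit_cnn(fx$spectra[perm, ], fx$reference[perm, ], epochs = 50, seed = 2)
  expect_equal(m1$fit$par$Wc, m3$fit$par$Wc, tolerance = 1e-8)
})

test_that("prediction refuses inputs whose width differs from the fitted one", {
  sp <- tiny_spectra(20, 30, seed = 8)
  ref <- tibble::tibble(id = sp$id, nr_percent = withr::with_seed(8, stats::runif(20, 0, 30)))
  m <- fit_pls(sp, ref, n_components = 3)
  narrower <- sp[, 1:20]
  expect_error(predict(m, narrower), class = "nircal_shape_error")
})
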