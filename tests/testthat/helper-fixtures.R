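# fixture builders and independent oracles used across the suite

tiny_spectra <- function(n = 5, p = 8, seed = 1, start = 1000, step = 2) {
  withr::with_seed(seed, {
    as_spectra(matrix(stats::runif(n * p), n),
               wavelengths = seq(start, by = step, length.out = p))
  })
}

# noiseless data whose content -> spectrum map is exactly affine
affine_fixture <- function(n = 30, seed = 1) {
  cfg <- synth_config(
    n_samples = n, seed = seed,
    n_interferents = 0, background_amplitude = 0,
    baseline = list(offset_sd = 0, slope_sd = 0),
    scatter = list(mult_sd = 0, add_sd = 0),
    noise_sd = 0
  )
  sim <- simulate_nir_dataset(cfg)
  list(spectra = sim$spectra, reference = sim$reference, cfg = cfg)
}

# planted-variable regression fixture for wavelength-selection recovery
planted_fixture <- function(seed, n = 80, p = 200, n_planted = 8,
                            beta_range = c(1.5, 2.5), noise_sd = 0.3) {
  withr::with_seed(seed, {
    planted <- sort(sample.int(p, n_planted))
    X <- matrix(stats::rnorm(n * p), n)
    beta <- numeric(p)
    beta[planted] <- stats::runif(n_planted, beta_range[1], beta_range[2])
    y <- as.numeric(X %*% beta + stats::rnorm(n, 0, noise_sd))
    wl <- seq(850, by = 2, length.out = p)
    sp <- as_spectra(X, wl)
    list(spectra = sp,
         reference = tibble::tibble(id = sp$id,
                                    nr_percent = pmin(pmax(y + 15, 0), 100)),
         planted_wl = wl[planted])
  })
}

# independent loop oracles
oracle_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}

oracle_r2 <- function(y, yhat) {
  sse <- 0; sst <- 0; m <- sum(y) / length(y)
  for (i in seq_along(y)) {
    sse <- sse + (y[i] - yhat[i])^2
    sst <- sst + (y[i] - m)^2
  }
  1 - sse / sst
}

# plain double-loop max-min selection, independent of the package's version
oracle_maxmin <- function(D, n_train) {
  n <- nrow(D)
  best <- c(NA, NA); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_train) {
    cand_best <- NA; cand_d <- -Inf
    for (i in setdiff(1:n, sel)) {
      di <- Inf
      for (j in sel) di <- min(di, D[i, j])
      if (di > cand_d) { cand_d <- di; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sort(sel)
}

oracle_spxy_D <- function(X, y) {
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(y))
  D <- dx / max(dx)
  if (max(dy) > 0) D <- D + dy / max(dy)
  D
}
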