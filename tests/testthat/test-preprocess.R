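test_that("moving-window smoothing averages a centered, edge-truncated window", {
  const <- as_spectra(matrix(3, 2, 7), seq(1000, by = 2, length.out = 7))
  expect_equal(mws(const), const)

  spike <- as_spectra(matrix(c(0, 0, 5, 0, 0), 1), seq(1000, by = 2, length.out = 5))
  sm <- spectra_matrix(mws(spike, 5))
  expect_equal(unname(sm[1, 3]), 1)           # interior: mean of full window
  expect_equal(unname(sm[1, 1]), 5 / 3)       # edge: truncated window of 3

  expect_error(mws(spike, 4), class = "nircal_parameter_error")

  # white noise variance shrinks by the window size at interior points
  wl <- seq(850, by = 0.016, length.out = 100000)
  noisy <- withr::with_seed(1, as_spectra(matrix(stats::rnorm(100000), 1), wl))
  inner <- spectra_matrix(mws(noisy, 5))[1, 3:99998]
  expect_lt(abs(stats::var(inner) - 1 / 5), 0.05 / 5)
})

test_that("SNV standardizes each spectrum by its own mean and n-1 sd", {
  sp <- as_spectra(matrix(c(1, 2, 3), 1), c(1000, 1002, 1004))
  expect_equal(unname(spectra_matrix(snv(sp))), matrix(c(-1, 0, 1), 1))

  rs <- tiny_spectra(6, 40, seed = 3)
  out <- spectra_matrix(snv(rs))
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, stats::sd) - 1) < 1e-12))

  # invariance under per-spectrum affine transforms with positive scale
  m <- spectra_matrix(rs)
  shifted <- as_spectra(2.5 * m + 7, wavelengths(rs), ids = rs$id)
  expect_equal(snv(shifted), snv(rs))

  flat <- as_spectra(matrix(1, 2, 4), seq(1000, by = 2, length.out = 4),
                     ids = c("ok", "flat"))
  expect_error(snv(flat), class = "nircal_degenerate_error")
  expect_error(snv(flat), "flat|ok")
})

test_that("MSC regresses on the reference and inverts the fitted affine distortion", {
  rs <- tiny_spectra(5, 30, seed = 8)
  refv <- colMeans(spectra_matrix(rs))
  same <- as_spectra(matrix(refv, 1), wavelengths(rs))
  expect_equal(unname(spectra_matrix(msc(same, refv))[1, ]), unname(refv))

  distorted <- as_spectra(matrix(2 * refv + 1, 1), wavelengths(rs))
  expect_equal(unname(spectra_matrix(msc(distorted, refv))[1, ]), unname(refv))

  # correcting validation data with the training reference is not
  # self-referenced correction (guards against leakage)
  val <- tiny_spectra(4, 30, seed = 9)
  expect_false(isTRUE(all.equal(msc(val, refv), msc(val))))
})

test_that("first derivative removes additive baselines on a midpoint grid", {
  wl <- seq(1000, by = 2, length.out = 10)
  const <- as_spectra(matrix(4, 1, 10), wl)
  expect_true(all(spectra_matrix(fd(const)) == 0))

  lin <- as_spectra(matrix(0.01 * wl, 1), wl)
  out <- fd(lin)
  expect_true(all(abs(spectra_matrix(out) - 0.01) < 1e-12))
  expect_equal(length(wavelengths(out)), 9)
  expect_equal(wavelengths(out)[1], 1001)

  rs <- tiny_spectra(3, 10, seed = 2)
  shifted <- as_spectra(spectra_matrix(rs) + 5, wavelengths(rs), ids = rs$id)
  expect_equal(fd(shifted), fd(rs))

  irr <- as_spectra(matrix(1:4, 1), c(1000, 1002, 1005, 1010))
  expect_error(fd(irr), class = "nircal_grid_error")
})

test_that("pretreatment chains parse, execute in printed order, and carry fitted state", {
  expect_equal(parse_chain("None"), character(0))
  expect_equal(parse_chain("MWS-FD"), c("MWS", "FD"))
  expect_error(parse_chain("MWS-XYZ"), class = "nircal_parameter_error")
  expect_error(parse_chain("MWS-MWS"), class = "nircal_parameter_error")

  rs <- tiny_spectra(6, 30, seed = 5)
  expect_equal(fit_chain(rs, "None")$train, rs)

  # SNV last: processed rows are standardized
  out <- spectra_matrix(fit_chain(rs, "MWS-SNV")$train)
  expect_true(all(abs(rowMeans(out)) < 1e-12))

  # MWS-FD on a noisy linear spectrum is closer to constant than plain FD
  wl <- seq(1000, by = 2, length.out = 200)
  noisy <- withr::with_seed(4, as_spectra(matrix(0.01 * wl + stats::rnorm(200, 0, 0.05), 1), wl))
  sd_smoothed <- stats::sd(spectra_matrix(fit_chain(noisy, "MWS-FD")$train))
  sd_plain <- stats::sd(spectra_matrix(fd(noisy)))
  expect_lt(sd_smoothed, sd_plain)

  # order matters: MWS-FD != FD then MWS here
  a <- fit_chain(noisy, "MWS-FD")$train
  b <- mws(fd(noisy))
  expect_false(isTRUE(all.equal(spectra_matrix(a), spectra_matrix(b))))

  # applying an MSC chain whose reference was stripped is a state error
  cf <- fit_chain(rs, "MWS-MSC")
  expect_equal(length(cf$msc_reference), 30)
  broken <- cf; broken$msc_reference <- NULL
  expect_error(apply_chain(rs, broken), class = "nircal_state_error")

  # train-fitted chain applies train parameters to validation data
  val <- tiny_spectra(4, 30, seed = 6)
  expect_equal(apply_chain(val, cf), msc(mws(val), cf$msc_reference))
})

test_that("all pretreatment operators are row-independent", {
  rs <- tiny_spectra(8, 25, seed = 7)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  for (op in list(mws, snv, function(s) msc(s, colMeans(spectra_matrix(rs))), fd)) {
    expect_equal(op(rs[perm, ]), op(rs)[perm, ])
  }
})
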