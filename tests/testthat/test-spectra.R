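test_that("wide and long file layouts round-trip and agree", {
  sp <- tiny_spectra(3, 5)
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, wide, "wide")
  write_spectra(sp, long, "long")
  expect_equal(read_spectra(wide, "wide"), sp)
  expect_equal(read_spectra(long, "long"), sp)
  expect_equal(read_spectra(long, "long"), read_spectra(wide, "wide"))

  ref <- tibble::tibble(id = sp$id, nr_percent = c(1, 10, 25))
  rf <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, rf)
  expect_equal(read_reference(rf), ref)
})

test_that("malformed spectra files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,900,880,950", "a,1,2,3"), f)
  expect_error(read_spectra(f), class = "nircal_format_error")

  writeLines(c("id,900,910,920", "a,1,x,3"), f)
  expect_error(read_spectra(f), class = "nircal_parse_error")

  # ragged long file: one (id, wavelength) pair missing
  writeLines(c("id,wavelength_nm,absorbance", "a,900,1", "a,910,2", "b,900,3"), f)
  expect_error(read_spectra(f, "long"), class = "nircal_format_error")

  expect_error(as_spectra(matrix(1, 1, 2), c(100, 200)),
               class = "nircal_format_error") # outside 850-2500
  expect_error(as_spectra(matrix(NA_real_, 1, 1), 1000),
               class = "nircal_format_error")
})

test_that("replicate averaging is an element-wise mean with the expected noise reduction", {
  sp <- tiny_spectra(4, 6)
  expect_equal(average_replicates(list(sp)), sp)

  zeros <- as_spectra(matrix(0, 2, 3), c(1000, 1002, 1004))
  twos <- as_spectra(matrix(2, 2, 3), c(1000, 1002, 1004))
  expect_equal(unname(spectra_matrix(average_replicates(list(zeros, twos)))),
               matrix(1, 2, 3))

  # permutation invariance in the list argument
  a <- tiny_spectra(3, 5, seed = 1); b <- tiny_spectra(3, 5, seed = 2)
  c3 <- tiny_spectra(3, 5, seed = 3)
  expect_equal(average_replicates(list(a, b, c3)),
               average_replicates(list(c3, a, b)))

  # three replicates with iid noise sd s -> averaged noise sd ~ s/sqrt(3)
  wl <- seq(850, by = 1, length.out = 1000)
  s <- 0.1
  reps <- withr::with_seed(7, lapply(1:3, function(i) {
    as_spectra(matrix(stats::rnorm(1000, 0, s), 1), wl, ids = "x")
  }))
  avg_sd <- stats::sd(spectra_matrix(average_replicates(reps))[1, ])
  expect_lt(abs(avg_sd - s / sqrt(3)), 0.1 * s / sqrt(3))

  mismatched <- tiny_spectra(3, 5, start = 1200)
  expect_error(average_replicates(list(a, mismatched)),
               class = "nircal_alignment_error")
})

test_that("grid resampling takes block means labeled by the block-left wavelength", {
  sp <- as_spectra(matrix(c(1, 2, 3, 4), 1), seq(1000, 1001.5, by = 0.5))
  out <- resample_spectra(sp, 1)
  expect_equal(unname(spectra_matrix(out)), matrix(c(1.5, 3.5), 1))
  expect_equal(wavelengths(out), c(1000, 1001))

  # 3300 points at 0.5 nm -> 825 points at 2 nm
  raw <- as_spectra(matrix(stats::rnorm(2 * 3300), 2),
                    seq(850, by = 0.5, length.out = 3300))
  rs <- resample_spectra(raw, 2)
  expect_equal(length(wavelengths(rs)), 825)
  expect_equal(wavelengths(rs)[1:3], c(850, 852, 854))
  expect_equal(max(wavelengths(rs)), 2498)
  # block means preserve each spectrum's global mean when k divides p
  expect_equal(rowMeans(spectra_matrix(rs)), rowMeans(spectra_matrix(raw)))

  const <- as_spectra(matrix(5, 1, 8), seq(1000, by = 0.5, length.out = 8))
  expect_true(all(spectra_matrix(resample_spectra(const, 2)) == 5))

  dec <- resample_spectra(sp, 1, method = "decimate")
  expect_equal(unname(spectra_matrix(dec)), matrix(c(1, 3), 1))

  expect_error(resample_spectra(sp, 0.75), class = "nircal_resolution_error")
})

test_that("content summaries report the conventional sample-set statistics", {
  ref <- tibble::tibble(id = c("a", "b", "c"), nr_percent = c(0, 10, 20))
  cs <- content_summary(ref)
  expect_equal(cs$mean, 10)
  expect_equal(cs$cv_percent, 100 * stats::sd(c(0, 10, 20)) / 10)
})
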