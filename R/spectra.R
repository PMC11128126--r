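#' Build a spectra tibble from a matrix
#'
#' The package represents a set of diffuse-reflectance NIR spectra as a wide
#' tibble: a character `id` column followed by one numeric column per
#' wavelength, named by the wavelength in nm (e.g. `"850"`, `"852"`).
#' All spectra functions take and return this shape so they chain with the
#' pipe.
#'
#' @param absorbance numeric matrix, samples in rows, wavelengths in columns
#'   (unitless absorbance, log 1/R).
#' @param wavelengths strictly increasing numeric vector of wavelengths in nm,
#'   one per column of `absorbance`, all within 850-2500 nm.
#' @param ids character vector of unique sample identifiers; defaults to
#'   `S001, S002, ...`.
#' @return a validated spectra tibble.
#' @export
#' @examples
#' as_spectra(matrix(runif(10), 2, 5), wavelengths = seq(1000, 1008, by = 2))
as_spectra <- function(absorbance, wavelengths, ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(absorbance)))
  if (length(wavelengths) != ncol(absorbance)) {
    rlang::abort("`wavelengths` length must equal the column count of `absorbance`.",
                 class = "nircal_shape_error")
  }
  out <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(out) <- format_wl(wavelengths)
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids)), out)
  validate_spectra(out)
}

format_wl <- function(wl) formatC(wl, format = "fg", width = 1, digits = 15)

#' Extract the absorbance matrix / wavelength grid from a spectra tibble
#'
#' @param spectra a spectra tibble (see [as_spectra()]).
#' @return `spectra_matrix()`: a numeric matrix with sample ids as rownames;
#'   `wavelengths()`: the numeric wavelength grid in nm.
#' @export
spectra_matrix <- function(spectra) {
  m <- as.matrix(spectra[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- spectra$id
  m
}

#' @rdname spectra_matrix
#' @export
wavelengths <- function(spectra) {
  as.numeric(names(spectra)[-1])
}

grid_step <- function(wl) {
  d <- diff(wl)
  if (length(d) == 0) return(NA_real_)
  if (max(d) - min(d) > 1e-9) return(NA_real_) # irregular
  mean(d)
}

#' Validate a spectra tibble
#'
#' Checks the container invariants: unique ids, strictly increasing wavelength
#' grid within 850-2500 nm, finite absorbance values.
#'
#' @param spectra a spectra tibble.
#' @param range allowed wavelength range in nm.
#' @return the input, invisibly usable in a pipe (returned visibly).
#' @export
validate_spectra <- function(spectra, range = c(850, 2500)) {
  if (!is.data.frame(spectra) || names(spectra)[1] != "id") {
    rlang::abort("spectra must be a tibble whose first column is `id`.",
                 class = "nircal_format_error")
  }
  wl <- suppressWarnings(as.numeric(names(spectra)[-1]))
  if (anyNA(wl)) {
    rlang::abort("non-numeric wavelength column names.", class = "nircal_format_error")
  }
  if (length(wl) == 0 || any(diff(wl) <= 0)) {
    rlang::abort("wavelengths must be strictly increasing.", class = "nircal_format_error")
  }
  if (min(wl) < range[1] || max(wl) > range[2]) {
    rlang::abort(sprintf("wavelengths must lie within [%g, %g] nm.", range[1], range[2]),
                 class = "nircal_format_error")
  }
  if (anyDuplicated(spectra$id)) {
    rlang::abort("sample ids must be unique.", class = "nircal_format_error")
  }
  m <- as.matrix(spectra[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) {
    rlang::abort("absorbance values must all be finite numbers.",
                 class = "nircal_format_error")
  }
  spectra
}

#' Read / write spectra as delimited text
#'
#' Wide layout: header `id, <wl1>, <wl2>, ...` with wavelengths in nm.
#' Long layout: columns `id, wavelength_nm, absorbance`. Values written at
#' full precision round-trip bit-identically.
#'
#' @param path file path (CSV).
#' @param layout `"wide"` or `"long"`.
#' @return `read_spectra()` a validated spectra tibble; `write_spectra()` the
#'   input, invisibly.
#' @export
read_spectra <- function(path, layout = c("wide", "long")) {
  layout <- rlang::arg_match(layout)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "nircal_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  if (layout == "long") {
    need <- c("id", "wavelength_nm", "absorbance")
    if (!all(need %in% names(df))) {
      rlang::abort("long layout needs columns id, wavelength_nm, absorbance.",
                   class = "nircal_format_error")
    }
    wl <- sort(unique(df$wavelength_nm))
    wide <- tidyr::pivot_wider(df, id_cols = "id",
                               names_from = "wavelength_nm",
                               values_from = "absorbance")
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (anyNA(m)) {
      rlang::abort("ragged long file: not every (id, wavelength) pair present.",
                   class = "nircal_format_error")
    }
    ord <- order(as.numeric(names(wide)[-1]))
    return(as_spectra(m[, ord, drop = FALSE], wl, ids = wide$id))
  }
  if (names(df)[1] != "id") {
    rlang::abort("wide layout needs `id` as the first column.",
                 class = "nircal_format_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    rlang::abort(sprintf("non-numeric absorbance in column '%s'.", names(df)[-1][bad]),
                 class = "nircal_parse_error")
  }
  as_spectra(m, as.numeric(names(df)[-1]), ids = df$id)
}

#' @rdname read_spectra
#' @param spectra a spectra tibble.
#' @export
write_spectra <- function(spectra, path, layout = c("wide", "long")) {
  layout <- rlang::arg_match(layout)
  validate_spectra(spectra)
  if (layout == "wide") {
    readr::write_csv(spectra, path)
  } else {
    long <- tidyr::pivot_longer(spectra, -"id",
                                names_to = "wavelength_nm",
                                values_to = "absorbance")
    long$wavelength_nm <- as.numeric(long$wavelength_nm)
    readr::write_csv(long, path)
  }
  invisible(spectra)
}

#' Read / write a reference panel
#'
#' A reference panel holds the wet-chemistry ground truth: columns
#' `id`, `nr_percent` (natural-rubber content as % of root dry mass,
#' within \[0, 100\]).
#'
#' @param path CSV path with columns `id, nr_percent`.
#' @return a reference tibble.
#' @export
read_reference <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_reference(df)
}

#' @rdname read_reference
#' @param reference a reference tibble.
#' @export
write_reference <- function(reference, path) {
  readr::write_csv(validate_reference(reference), path)
  invisible(reference)
}

#' @rdname read_reference
#' @export
validate_reference <- function(reference) {
  if (!all(c("id", "nr_percent") %in% names(reference))) {
    rlang::abort("reference needs columns id, nr_percent.", class = "nircal_format_error")
  }
  y <- reference$nr_percent
  if (any(!is.finite(y)) || any(y < 0) || any(y > 100)) {
    rlang::abort("nr_percent must be finite and within [0, 100].",
                 class = "nircal_format_error")
  }
  if (anyDuplicated(reference$id)) {
    rlang::abort("reference ids must be unique.", class = "nircal_format_error")
  }
  tibble::as_tibble(reference)
}

check_aligned <- function(spectra, reference) {
  if (!identical(as.character(spectra$id), as.character(reference$id))) {
    rlang::abort("spectra and reference must carry the same ids in the same order.",
                 class = "nircal_alignment_error")
  }
  invisible(TRUE)
}

#' Average replicate spectra
#'
#' Instrument practice re-loads each sample several times (three in a typical
#' dried-root protocol) and keeps the element-wise mean spectrum, cutting
#' iid noise by 1/sqrt(k).
#'
#' @param sets a list of spectra tibbles sharing ids (same order) and grid.
#' @return a spectra tibble of element-wise means.
#' @export
average_replicates <- function(sets) {
  if (!is.list(sets) || length(sets) < 1 || is.data.frame(sets)) {
    rlang::abort("`sets` must be a non-empty list of spectra tibbles.",
                 class = "nircal_alignment_error")
  }
  ref <- sets[[1]]
  validate_spectra(ref)
  for (s in sets[-1]) {
    validate_spectra(s)
    if (!identical(names(s), names(ref)) || !identical(s$id, ref$id)) {
      rlang::abort("all replicate sets must share ids (order) and wavelength grid.",
                   class = "nircal_alignment_error")
    }
  }
  acc <- Reduce(`+`, lapply(sets, spectra_matrix))
  as_spectra(acc / length(sets), wavelengths(ref), ids = ref$id)
}

#' Resample a spectra tibble to a coarser wavelength grid
#'
#' Non-overlapping block means of `k = target_step / source_step` consecutive
#' points, labeled by the block-left wavelength. Under this half-open
#' \[850, 2500) convention a 3300-point grid at 0.5 nm becomes 825 points at
#' 2 nm, the usual working resolution for dried-root spectra. Block means (the
#' default) also reduce noise; `method = "decimate"` keeps the first point of
#' each block instead.
#'
#' @param spectra a spectra tibble on a regular grid.
#' @param target_step target spacing in nm; must be a positive integer
#'   multiple of the source spacing.
#' @param method `"block_mean"` (default) or `"decimate"`.
#' @return a spectra tibble on the coarser grid.
#' @export
resample_spectra <- function(spectra, target_step, method = c("block_mean", "decimate")) {
  method <- rlang::arg_match(method)
  validate_spectra(spectra)
  wl <- wavelengths(spectra)
  step <- grid_step(wl)
  if (is.na(step)) {
    rlang::abort("resampling needs a regular source grid.", class = "nircal_grid_error")
  }
  ratio <- target_step / step
  if (target_step <= 0 || abs(ratio - round(ratio)) > 1e-9) {
    rlang::abort("target_step must be a positive integer multiple of the source step.",
                 class = "nircal_resolution_error")
  }
  k <- as.integer(round(ratio))
  p <- length(wl)
  n_blocks <- p %/% k
  if (n_blocks < 1) {
    rlang::abort("target_step too coarse for this grid.", class = "nircal_resolution_error")
  }
  m <- spectra_matrix(spectra)[, seq_len(n_blocks * k), drop = FALSE]
  if (method == "block_mean") {
    grp <- rep(seq_len(n_blocks), each = k)
    out <- t(rowsum(t(m), grp) / k)
  } else {
    out <- m[, (seq_len(n_blocks) - 1L) * k + 1L, drop = FALSE]
  }
  new_wl <- wl[(seq_len(n_blocks) - 1L) * k + 1L] # block-left labels
  as_spectra(out, new_wl, ids = spectra$id)
}

#' Summary statistics of a reference panel
#'
#' The descriptive statistics conventionally tabulated for a calibration
#' sample set: max, min, median, mean, standard deviation and coefficient of
#' variation of the rubber content.
#'
#' @param reference a reference tibble.
#' @return a one-row tibble.
#' @export
content_summary <- function(reference) {
  validate_reference(reference)
  y <- reference$nr_percent
  tibble::tibble(
    n = length(y),
    maximum = max(y), minimum = min(y), median = stats::median(y),
    mean = mean(y), sd = stats::sd(y),
    cv_percent = cv_percent(mean(y), stats::sd(y))
  )
}

#' Coefficient of variation in percent
#'
#' @param mean,sd summary statistics of the content distribution.
#' @return `100 * sd / mean`.
#' @export
cv_percent <- function(mean, sd) 100 * sd / mean
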