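round_half_up <- function(x) floor(x + 0.5)

# deterministic max-min selection on a precomputed distance matrix;
# ties broken by lowest index
maxmin_select <- function(D, n_train) {
  n <- nrow(D)
  dmax <- max(D)
  if (dmax <= 0) {
    rlang::abort("all samples identical: distances degenerate.",
                 class = "nircal_degenerate_error")
  }
  seedpair <- which(D == dmax, arr.ind = TRUE)
  seedpair <- seedpair[order(seedpair[, 1], seedpair[, 2]), , drop = FALSE]
  sel <- sort(unname(seedpair[1, ]))
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    mind <- apply(D[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(mind)]) # which.max -> first (lowest index) on ties
  }
  sel[seq_len(n_train)]
}

split_result <- function(ids, train_idx, method, ratio) {
  part <- ifelse(seq_along(ids) %in% train_idx, "train", "validation")
  res <- tibble::tibble(id = ids, partition = part)
  structure(res, method = method, ratio = ratio,
            class = c("nir_split", class(res)))
}

#' SPXY partitioning of a sample set
#'
#' Sample-set partitioning based on joint x-y distances: pairwise Euclidean
#' distances are computed on the spectra (`dx`) and on the reference values
#' (`dy`), each normalized by its maximum, and summed. The most distant pair
#' seeds the training set, which then grows by the max-min rule (repeatedly
#' adding the sample whose minimum distance to the current training set is
#' largest) until `round(ratio * n)` samples — rounding half up, so 125
#' samples at 3:1 give 94/31 and 117 give 88/29. The remainder is the
#' validation set. The procedure is fully deterministic; ties are broken by
#' lowest sample index.
#'
#' @param spectra,reference aligned tibbles (the spectra should already carry
#'   the pretreatment used for modeling).
#' @param ratio training fraction, default 0.75 (a 3:1 split).
#' @return a `nir_split` tibble with columns `id`, `partition`.
#' @export
spxy_split <- function(spectra, reference, ratio = 0.75) {
  d <- model_xy(spectra, reference)
  n <- nrow(d$X)
  if (n < 4) rlang::abort("splitting needs n >= 4.", class = "nircal_parameter_error")
  dx <- as.matrix(stats::dist(d$X))
  dy <- as.matrix(stats::dist(d$y))
  if (max(dx) <= 0) {
    rlang::abort("all spectra identical: distances degenerate.",
                 class = "nircal_degenerate_error")
  }
  D <- dx / max(dx)
  if (max(dy) > 0) D <- D + dy / max(dy) # constant-y: dy term defined as 0
  tr <- maxmin_select(D, round_half_up(ratio * n))
  split_result(spectra$id, tr, "SPXY", ratio)
}

#' Kennard-Stone partitioning (x-distances only)
#'
#' The x-space-only baseline that SPXY extends: identical max-min selection
#' on spectra distances alone.
#'
#' @inheritParams spxy_split
#' @return a `nir_split` tibble.
#' @export
ks_split <- function(spectra, ratio = 0.75) {
  validate_spectra(spectra)
  X <- spectra_matrix(spectra)
  n <- nrow(X)
  if (n < 4) rlang::abort("splitting needs n >= 4.", class = "nircal_parameter_error")
  dx <- as.matrix(stats::dist(X))
  tr <- maxmin_select(dx / max(dx), round_half_up(ratio * n))
  split_result(spectra$id, tr, "KS", ratio)
}

#' Partition helper accessors
#'
#' @param split a `nir_split`.
#' @return character vectors of ids.
#' @export
train_ids <- function(split) split$id[split$partition == "train"]

#' @rdname train_ids
#' @export
validation_ids <- function(split) split$id[split$partition == "validation"]

apply_split <- function(spectra, reference, split, which = c("train", "validation")) {
  which <- rlang::arg_match(which)
  keep <- split$partition == which
  list(spectra = spectra[keep, , drop = FALSE],
       reference = reference[keep, , drop = FALSE])
}
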