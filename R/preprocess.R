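#' Lung CT display window
#'
#' @param width window width in HU (default 1700).
#' @param level window level in HU (default -600). The clip interval is
#'   `[level - width/2, level + width/2]`, i.e. `[-1450, 250]` HU by default.
#' @return an object of class `window_config`.
#' @export
window_config <- function(width = 1700, level = -600) {
  if (width <= 0) stop("window width must be positive")
  structure(list(width = width, level = level), class = "window_config")
}

#' Clip to a CT window and normalize to \[0, 1\]
#'
#' `out = (clip(image, lo, hi) - lo) / width` with
#' `lo = level - width/2`, `hi = level + width/2`.
#'
#' By default the normalized image is snapped to a `2^-24` fixed-point grid
#' (a perturbation below 6e-8, finer than single precision). On that grid
#' the residual `sparse - full` and the correction `sparse - residual` are
#' exact in double arithmetic, so residual round-trips reproduce the
#' full-view image bit for bit.
#'
#' @param image_HU numeric matrix in HU.
#' @param window a [window_config()].
#' @param quantize snap the output to the `2^-24` grid (default `TRUE`).
#' @return matrix with values in \[0, 1\].
#' @export
apply_window <- function(image_HU, window = window_config(),
                         quantize = TRUE) {
  if (!all(is.finite(image_HU))) stop("image contains non-finite values")
  lo <- window$level - window$width / 2
  hi <- window$level + window$width / 2
  out <- (pmin(pmax(image_HU, lo), hi) - lo) / window$width
  if (quantize) out <- round(out * 16777216) / 16777216
  out
}

#' Build a residual training pair
#'
#' The network's training target is the pure streak-artifact image. Following
#' the convention that the postprocessed image is the prediction subtracted
#' from the input, the stored label is `residual = sparse - full`, so that
#' `sparse - residual == full`. (The opposite sign convention,
#' `full - sparse`, is equivalent up to sign; this package fixes this one.)
#'
#' @param full_norm,sparse_norm windowed/normalized full-view and sparse-view
#'   images of identical shape.
#' @param view_count,subject_id metadata carried on the pair.
#' @return an object of class `residual_pair` with fields `sparse`,
#'   `residual_label`, `view_count`, `subject_id`.
#' @export
make_residual_pair <- function(full_norm, sparse_norm, view_count,
                               subject_id = NA_character_) {
  if (!identical(dim(full_norm), dim(sparse_norm)))
    stop("full and sparse images must have the same shape")
  structure(list(sparse = sparse_norm,
                 residual_label = sparse_norm - full_norm,
                 view_count = as.integer(view_count),
                 subject_id = subject_id),
            class = "residual_pair")
}

#' Apply a predicted residual correction
#'
#' `postprocessed = clip(sparse - predicted_residual, 0, 1)`; with a perfect
#' prediction the full-view image is recovered. Clipping keeps the output in
#' the normalized display range so SSIM's data range stays valid.
#'
#' @param sparse_norm normalized sparse-view image.
#' @param predicted_residual predicted artifact image, same shape.
#' @param clip clip the result to \[0, 1\] (default `TRUE`).
#' @return postprocessed image.
#' @export
apply_residual_correction <- function(sparse_norm, predicted_residual,
                                      clip = TRUE) {
  if (!identical(dim(sparse_norm), dim(predicted_residual)))
    stop("shape mismatch between sparse image and predicted residual")
  out <- sparse_norm - predicted_residual
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Split subjects into train/validation/test sets
#'
#' The split is decided per subject, never per image, so no subject's slices
#' can leak across partitions. Partition sizes are `round(n * fractions)`
#' with the last partition absorbing the remainder.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param fractions numeric vector summing to 1, named or in
#'   (train, validation, test) order.
#' @param seed integer seed; the same seed reproduces the split.
#' @return an object of class `dataset_split`: list of disjoint id vectors
#'   `train`, `validation`, `test`.
#' @export
split_cohort <- function(subject_ids, fractions = c(train = 12 / 22,
                                                    validation = 2 / 22,
                                                    test = 8 / 22),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  n <- length(subject_ids)
  sizes <- round(n * fractions)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  if (any(sizes < 0) || n < sum(fractions > 0))
    stop("fewer subjects than nonzero partitions")
  perm <- with_seed(seed, sample(subject_ids))
  bounds <- cumsum(sizes)
  out <- list(train = perm[seq_len(sizes[1])],
              validation = if (sizes[2] > 0)
                perm[(bounds[1] + 1):bounds[2]] else character(0),
              test = if (sizes[3] > 0)
                perm[(bounds[2] + 1):bounds[3]] else character(0))
  stopifnot(!anyDuplicated(unlist(out)))
  structure(out, class = "dataset_split")
}

#' Windowed view series
#'
#' Applies the lung window to every reconstruction of a [make_view_series()]
#' result.
#'
#' @param series a `view_series`.
#' @param window a [window_config()].
#' @return the series with normalized reconstructions.
#' @export
window_view_series <- function(series, window = window_config()) {
  series$reconstructions <- lapply(series$reconstructions, apply_window,
                                   window = window)
  series$windowed <- TRUE
  series
}

#' Residual pairs from a windowed view series
#'
#' @param series a windowed `view_series` (see [window_view_series()]).
#' @param view_counts sparse view levels to pair against the full-view
#'   reference.
#' @return list of [make_residual_pair()] objects.
#' @export
series_residual_pairs <- function(series,
                                  view_counts = setdiff(series$view_counts,
                                                        max(series$view_counts))) {
  full <- series$reconstructions[[as.character(max(series$view_counts))]]
  lapply(view_counts, function(v)
    make_residual_pair(full, series$reconstructions[[as.character(v)]], v,
                       series$subject_id))
}
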