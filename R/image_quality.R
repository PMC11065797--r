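#' Mean squared error between two images
#'
#' @param image_a,image_b numeric matrices of identical shape.
#' @return mean of squared pixel differences.
#' @export
mse <- function(image_a, image_b) {
  if (!identical(dim(image_a), dim(image_b))) stop("shape mismatch")
  mean((image_a - image_b)^2)
}

# 1-d gaussian kernel, normalized
gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# banded matrix implementing a "valid" 1-d gaussian filter along rows
gaussian_band <- function(n, kernel) {
  s <- length(kernel)
  m <- matrix(0, n - s + 1, n)
  for (i in seq_len(n - s + 1)) m[i, i:(i + s - 1)] <- kernel
  m
}

# separable valid-region gaussian filtering of a matrix
gfilter <- function(x, gl, gr) gl %*% x %*% gr

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with Gaussian-weighted 11x11 local windows (sigma 1.5),
#' constants `K1 = 0.01`, `K2 = 0.03`, averaged over the valid region of the
#' image.
#'
#' @param image_a,image_b numeric matrices of identical shape, at least
#'   11x11, on the scale given by `data_range`.
#' @param data_range dynamic range of the data (1 for normalized images).
#' @param K1,K2 stability constants.
#' @return scalar SSIM in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(image_a, image_b, data_range = 1.0, K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(image_a), dim(image_b))) stop("shape mismatch")
  if (data_range <= 0) stop("data_range must be positive")
  if (any(dim(image_a) < 11)) stop("images must be at least 11x11")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  k <- gaussian_kernel()
  gl <- gaussian_band(nrow(image_a), k)
  gr <- t(gaussian_band(ncol(image_a), k))
  mu_a <- gfilter(image_a, gl, gr)
  mu_b <- gfilter(image_b, gl, gr)
  va <- gfilter(image_a^2, gl, gr) - mu_a^2
  vb <- gfilter(image_b^2, gl, gr) - mu_b^2
  cab <- gfilter(image_a * image_b, gl, gr) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}

#' Mean with 95% confidence interval
#'
#' Student-t two-sided 95% interval of the mean over per-image metric values,
#' the aggregation used for MSE/SSIM result tables.
#'
#' @param values numeric vector, `length >= 2`.
#' @return an object of class `iq_summary`: list with `mean`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
summarize_iq <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  structure(list(mean = m, ci_low = m - half, ci_high = m + half, n = n),
            class = "iq_summary")
}

#' @export
print.iq_summary <- function(x, ...) {
  cat(sprintf("%.6g [%.6g, %.6g] (n = %d)\n", x$mean, x$ci_low, x$ci_high,
              x$n))
  invisible(x)
}

#' Per-image image-quality records for a windowed view series
#'
#' Computes MSE and SSIM of each sparse (or postprocessed) reconstruction
#' against the full-view reference.
#'
#' @param series a windowed `view_series`.
#' @param processed optional named list (by view count) of postprocessed
#'   images; when supplied, records are emitted for the `processed` arm,
#'   otherwise for the `sparse` arm.
#' @return data frame with columns `subject_id`, `view_count`, `arm`, `mse`,
#'   `ssim`.
#' @export
iq_records <- function(series, processed = NULL) {
  full <- series$reconstructions[[as.character(max(series$view_counts))]]
  views <- setdiff(series$view_counts, max(series$view_counts))
  arm <- if (is.null(processed)) "sparse" else "processed"
  rows <- lapply(views, function(v) {
    img <- if (is.null(processed)) series$reconstructions[[as.character(v)]]
           else processed[[as.character(v)]]
    data.frame(subject_id = series$subject_id, view_count = v, arm = arm,
               mse = mse(img, full), ssim = ssim(img, full),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
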