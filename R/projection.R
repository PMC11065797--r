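#' Parallel-beam acquisition geometry
#'
#' Describes the simulated scanner used to turn a slice into a sinogram: the
#' number of full-sampling views, the half-open angular range, and the
#' detector count. The defaults mirror the study setup: 2,048 views evenly
#' spaced over \[0, 180) degrees, parallel beam, Ram-Lak (ramp) filter.
#'
#' @param n_views_full number of projection angles at full sampling.
#' @param n_detectors detector count; defaults (when an image size is supplied
#'   to [forward_project()]) to the smallest count covering the image
#'   diagonal, which avoids truncation artifacts.
#' @param angular_range half-open angle interval in radians.
#' @param beam beam model; only `"parallel"` is implemented.
#' @param filter_name reconstruction filter; only `"ramp"` is implemented.
#' @return an object of class `ct_geometry`.
#' @export
#' @examples
#' geom <- ct_geometry(n_views_full = 2048)
#' geom$n_views_full
ct_geometry <- function(n_views_full = 2048L, n_detectors = NULL,
                        angular_range = c(0, pi), beam = "parallel",
                        filter_name = "ramp") {
  stopifnot(n_views_full >= 1)
  beam <- match.arg(beam, "parallel")
  filter_name <- match.arg(filter_name, "ramp")
  structure(list(n_views_full = as.integer(n_views_full),
                 n_detectors = if (is.null(n_detectors)) NULL
                               else as.integer(n_detectors),
                 angular_range = angular_range, beam = beam,
                 filter_name = filter_name),
            class = "ct_geometry")
}

# evenly spaced projection angles over the half-open range
projection_angles <- function(geometry, n_views = geometry$n_views_full) {
  a0 <- geometry$angular_range[1]
  a1 <- geometry$angular_range[2]
  a0 + (a1 - a0) * (seq_len(n_views) - 1) / n_views
}

#' Forward project an image to a sinogram
#'
#' Computes the discrete parallel-beam Radon transform of a square image:
#' row *k* of the result holds the line integrals (unit pixel steps, bilinear
#' sampling) at the *k*-th projection angle. The operation is linear in the
#' image.
#'
#' @param image square numeric matrix (e.g. HU values).
#' @param geometry a [ct_geometry()].
#' @param n_views number of views; defaults to the full sampling.
#' @return an object of class `sinogram` with fields `data`
#'   (`n_views x n_detectors`), `angles`, `geometry`, and the source
#'   image dimensions in `image_dim`.
#' @export
forward_project <- function(image, geometry = ct_geometry(),
                            n_views = geometry$n_views_full) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image)) stop("image must be square")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  n_det <- geometry$n_detectors
  diag_px <- ceiling(sqrt(2) * nrow(image))
  if (is.null(n_det)) n_det <- as.integer(diag_px + diag_px %% 2 + 1)
  if (n_det < diag_px) stop("n_detectors below the image diagonal")
  angles <- projection_angles(geometry, n_views)
  data <- cpp_radon(image, angles, n_det)
  structure(list(data = data, angles = angles, geometry = geometry,
                 image_dim = dim(image)),
            class = "sinogram")
}

#' Subsample sinogram views
#'
#' Keeps every (`n_views_full / n_views`)-th projection starting at the first
#' angle, so the retained angles remain evenly spaced over the angular range.
#' `n_views` must divide the number of rows.
#'
#' @param sinogram a `sinogram`.
#' @param n_views number of views to keep.
#' @return a `sinogram` with `n_views` rows.
#' @export
subsample_views <- function(sinogram, n_views) {
  stopifnot(inherits(sinogram, "sinogram"))
  nv <- nrow(sinogram$data)
  if (n_views < 1 || nv %% n_views != 0)
    stop("n_views must be a divisor of the full view count (", nv, ")")
  stride <- nv %/% n_views
  keep <- seq(1L, nv, by = stride)
  sinogram$data <- sinogram$data[keep, , drop = FALSE]
  sinogram$angles <- sinogram$angles[keep]
  sinogram
}

# frequency response of the discrete Ram-Lak filter: FFT of the real-space
# ramp kernel (value 1/4 at lag 0, -1/(pi n)^2 at odd lags), which avoids the
# DC bias of sampling |f| directly
ramp_filter <- function(n) {
  f <- numeric(n)
  f[1] <- 0.25
  odd <- seq(1, n / 2, by = 2)
  f[1 + odd] <- -1 / (pi * odd)^2
  f[n + 1 - odd] <- -1 / (pi * odd)^2
  2 * Re(stats::fft(f))
}

#' Reconstruct an image from a sinogram by filtered backprojection
#'
#' Ramp-filters each projection in the frequency domain (discrete Ram-Lak
#' kernel, zero-padded FFT) and backprojects with linear detector
#' interpolation onto the source grid. Output shape equals the forward
#' projection's source image shape.
#'
#' @param sinogram a `sinogram` produced by [forward_project()] (possibly
#'   subsampled with [subsample_views()]).
#' @return numeric matrix of the reconstructed image.
#' @export
fbp_reconstruct <- function(sinogram) {
  stopifnot(inherits(sinogram, "sinogram"))
  if (nrow(sinogram$data) < 1) stop("empty sinogram")
  n_det <- ncol(sinogram$data)
  pad <- max(64, 2^ceiling(log2(2 * n_det)))
  padded <- matrix(0, pad, nrow(sinogram$data))
  padded[seq_len(n_det), ] <- t(sinogram$data)
  filt <- ramp_filter(pad)
  fproj <- Re(stats::mvfft(stats::mvfft(padded) * filt, inverse = TRUE)) / pad
  fsino <- t(fproj[seq_len(n_det), , drop = FALSE])
  cpp_backproject(fsino, sinogram$angles, sinogram$image_dim[1],
                  sinogram$image_dim[2])
}

#' Reconstruct one slice at a set of view counts
#'
#' Forward projects the image once at full sampling, then reconstructs it at
#' every requested view count (each a divisor of the full count). The
#' full-view entry is the package's stand-in for artifact-free ground truth.
#'
#' @param image square numeric matrix in HU.
#' @param geometry a [ct_geometry()].
#' @param view_counts integer vector of view counts; the full view count is
#'   always included.
#' @param subject_id optional identifier carried through to the result.
#' @return an object of class `view_series`: list with `subject_id`,
#'   `view_counts`, and `reconstructions` (named list of matrices keyed by
#'   view count).
#' @export
make_view_series <- function(image, geometry = ct_geometry(),
                             view_counts = c(16L, 32L, 64L, 128L, 256L, 512L),
                             subject_id = NA_character_) {
  full <- geometry$n_views_full
  view_counts <- sort(unique(as.integer(c(view_counts, full))))
  if (any(full %% view_counts != 0))
    stop("all view counts must divide n_views_full")
  sino <- forward_project(image, geometry)
  recon <- lapply(view_counts, function(v)
    fbp_reconstruct(subsample_views(sino, v)))
  names(recon) <- as.character(view_counts)
  structure(list(subject_id = subject_id, view_counts = view_counts,
                 reconstructions = recon),
            class = "view_series")
}

#' @export
print.view_series <- function(x, ...) {
  cat("<view_series>", x$subject_id, "views:",
      paste(x$view_counts, collapse = ", "), "\n")
  invisible(x)
}
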