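#' Cohort configuration for the phantom generator
#'
#' @param n_subjects number of subjects (one representative slice each).
#' @param diseased_fraction proportion of subjects carrying a nodule; the
#'   diseased count is `round(n_subjects * diseased_fraction)`. The
#'   reader-study design of the emulated study uses 12/19.
#' @param image_size slice size in pixels (square). 512 is the full-scale
#'   size; 128 is the desk profile.
#' @param pixel_spacing mm per pixel. Default 0.7 mm (about a 36 cm field of
#'   view at 512 px, typical for chest CT); needed to realise 1--2 cm nodules
#'   in pixels.
#' @param seed base seed; per-subject seeds are derived from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 19L, diseased_fraction = 12 / 19,
                          image_size = 512L, pixel_spacing = 0.7,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, diseased_fraction >= 0, diseased_fraction <= 1,
            image_size >= 16, pixel_spacing > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 diseased_fraction = diseased_fraction,
                 image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing, seed = as.integer(seed)),
            class = "cohort_config")
}

# stamp a soft-edged disk onto an image; returns the modified image
stamp_disk <- function(img, cy, cx, radius, value, edge = 1) {
  H <- nrow(img); W <- ncol(img)
  r2 <- ceiling(radius + 3 * edge)
  ys <- max(1, floor(cy - r2)):min(H, ceiling(cy + r2))
  xs <- max(1, floor(cx - r2)):min(W, ceiling(cx + r2))
  if (!length(ys) || !length(xs)) return(img)
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  w <- 1 / (1 + exp((d - radius) / (edge / 2)))   # sigmoid edge profile
  patch <- img[ys, xs, drop = FALSE]
  img[ys, xs] <- patch + w * (value - patch)
  img
}

# mask of an ellipse on the pixel grid
ellipse_mask <- function(H, W, cy, cx, ry, rx, theta = 0) {
  y <- matrix(seq_len(H) - cy, H, W)
  x <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  if (theta != 0) {
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    x <- xr; y <- yr
  }
  (x / rx)^2 + (y / ry)^2 <= 1
}

#' Generate a single phantom slice
#'
#' Builds a 2-D chest-CT-like attenuation map in Hounsfield units: an
#' elliptical thorax of soft tissue (about 0 HU) on an air background
#' (-1000 HU), two low-density lung fields (about -800 HU) containing bright
#' curvilinear vessel-like structures, a vertebral body, and -- for diseased
#' subjects -- exactly one soft-tissue-density nodule with its exact binary
#' ground-truth mask. Nodules are soft-edged disks with diameters drawn from
#' 1.1--1.9 cm, inside the 1--2 cm range of the emulated cohort.
#'
#' @param subject_id identifier carried through the pipeline.
#' @param diseased logical; if `FALSE` the nodule mask is all-`FALSE`.
#' @param config a [cohort_config()].
#' @param seed integer seed; the same seed reproduces the slice bit-exactly.
#' @return an object of class `phantom_slice`: list with `subject_id`,
#'   `image` (HU matrix), `pixel_spacing`, `diseased`, `nodule_mask`
#'   (logical matrix) and `nodule_diameter` (cm, `NA` when healthy).
#' @export
generate_phantom <- function(subject_id, diseased, config = cohort_config(),
                             seed = derive_seed(config$seed, subject_id)) {
  n <- config$image_size
  sp <- config$pixel_spacing
  # a 1 cm nodule must fit inside a lung field
  min_r_px <- 10 / 2 / sp
  lung_rx <- 0.17 * n
  if (min_r_px > 0.75 * lung_rx)
    stop("image too small to contain a 1 cm nodule at pixel spacing ",
         sp, " mm")
  with_seed(seed, {
    img <- matrix(-1000, n, n)                       # air
    cy <- n / 2 + stats::rnorm(1, 0, 0.01 * n)
    cx <- n / 2 + stats::rnorm(1, 0, 0.01 * n)
    body_ry <- 0.34 * n * stats::runif(1, 0.95, 1.05)
    body_rx <- 0.45 * n * stats::runif(1, 0.95, 1.05)
    body <- ellipse_mask(n, n, cy, cx, body_ry, body_rx)
    img[body] <- 0 + stats::rnorm(sum(body), 0, 8)   # soft tissue + texture
    lungs <- vector("list", 2)
    for (s in 1:2) {
      side <- if (s == 1) -1 else 1
      lcx <- cx + side * 0.22 * n * stats::runif(1, 0.92, 1.08)
      lcy <- cy - 0.02 * n
      lry <- 0.26 * n * stats::runif(1, 0.92, 1.05)
      lrx <- lung_rx * stats::runif(1, 0.92, 1.05)
      lung <- ellipse_mask(n, n, lcy, lcx, lry, lrx, theta = side * 0.12)
      img[lung] <- -800 + stats::rnorm(sum(lung), 0, 12)
      lungs[[s]] <- list(mask = lung, cy = lcy, cx = lcx, ry = lry, rx = lrx,
                         side = side)
    }
    # vertebral body posterior to the lungs
    img_v <- stamp_disk(img, cy + 0.26 * n, cx, 0.05 * n, 700, edge = 1.5)
    img <- ifelse(body, img_v, img)
    # vessel trees: random walks from each hilum with tapering calibre
    for (s in 1:2) {
      lg <- lungs[[s]]
      n_vessels <- 6L + stats::rbinom(1, 4, 0.5)
      for (v in seq_len(n_vessels)) {
        py <- lg$cy + stats::rnorm(1, 0, 0.03 * n)
        px <- lg$cx - lg$side * lg$rx * 0.55
        dir <- stats::runif(1, -pi, pi)
        r0 <- stats::runif(1, 1.2, 2.6) * n / 256 + 0.8
        steps <- round(stats::runif(1, 0.5, 1.1) * lg$rx)
        for (st in seq_len(steps)) {
          dir <- dir + stats::rnorm(1, 0, 0.22)
          py <- py + sin(dir); px <- px + cos(dir)
          if (!ellipse_mask_point(lg, py, px, n)) break
          rad <- max(0.7, r0 * (1 - st / steps / 1.6))
          img <- stamp_disk(img, py, px, rad, -80, edge = 0.8)
        }
      }
    }
    nodule_mask <- matrix(FALSE, n, n)
    nodule_diameter <- NA_real_
    if (diseased) {
      nodule_diameter <- stats::runif(1, 1.1, 1.9)   # cm
      r_px <- nodule_diameter * 10 / 2 / sp
      lg <- lungs[[sample.int(2, 1)]]
      repeat {
        u <- stats::runif(1, 0, 2 * pi); rr <- sqrt(stats::runif(1))
        ny <- lg$cy + rr * (lg$ry - r_px - 2) * sin(u) * 0.9
        nx <- lg$cx + rr * (lg$rx - r_px - 2) * cos(u) * 0.9
        if (ellipse_mask_point(lg, ny, nx, n, shrink = (r_px + 1.5))) break
      }
      img <- stamp_disk(img, ny, nx, r_px, 20, edge = 1.2)
      d <- sqrt(outer((seq_len(n) - ny)^2, (seq_len(n) - nx)^2, "+"))
      nodule_mask <- d <= r_px
    }
    img <- pmin(pmax(img, -1024), 3000)
    structure(list(subject_id = subject_id, image = img, pixel_spacing = sp,
                   diseased = diseased, nodule_mask = nodule_mask,
                   nodule_diameter = nodule_diameter),
              class = "phantom_slice")
  })
}

# is point (y, x) inside the (rotated) lung ellipse, optionally shrunk by a
# margin in pixels
ellipse_mask_point <- function(lg, y, x, n, shrink = 0) {
  th <- lg$side * 0.12
  dx <- x - lg$cx; dy <- y - lg$cy
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  (xr / (lg$rx - shrink))^2 + (yr / (lg$ry - shrink))^2 <= 1
}

#' Nodule equivalent diameter in cm
#'
#' Equivalent diameter of a binary mask: the diameter of the disk with the
#' same pixel area, converted to cm through the pixel spacing.
#'
#' @param mask logical matrix.
#' @param pixel_spacing mm per pixel.
#' @return diameter in cm (0 for an empty mask).
#' @export
equivalent_diameter_cm <- function(mask, pixel_spacing) {
  a <- sum(mask)
  2 * sqrt(a / pi) * pixel_spacing / 10
}

#' Generate a phantom cohort
#'
#' One slice per subject (mirroring a representative image per scan), with
#' `round(n_subjects * diseased_fraction)` diseased subjects and unique
#' subject ids. Deterministic for a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @return list of [generate_phantom()] slices.
#' @export
generate_cohort <- function(config = cohort_config()) {
  n <- config$n_subjects
  n_dis <- round(n * config$diseased_fraction)
  ids <- sprintf("S%03d", seq_len(n))
  status <- c(rep(TRUE, n_dis), rep(FALSE, n - n_dis))
  lapply(seq_len(n), function(i)
    generate_phantom(ids[i], status[i], config,
                     seed = derive_seed(config$seed, ids[i])))
}

#' Generate several slice variants for one subject
#'
#' The training path of the emulated study uses many slices per scan while
#' the reader study uses one. This helper emulates a slice stack by drawing
#' independent phantom variants that share the subject id and disease status
#' (seeded per slice).
#'
#' @param subject_id,diseased,config as in [generate_phantom()].
#' @param n_slices number of variants.
#' @param seed base seed for the stack.
#' @return list of `phantom_slice` objects.
#' @export
generate_slice_stack <- function(subject_id, diseased,
                                 config = cohort_config(), n_slices = 1L,
                                 seed = derive_seed(config$seed, subject_id)) {
  lapply(seq_len(n_slices), function(k)
    generate_phantom(subject_id, diseased, config,
                     seed = derive_seed(seed, paste0("slice", k))))
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat("<phantom_slice>", x$subject_id,
      if (x$diseased) sprintf("diseased (%.2f cm nodule)", x$nodule_diameter)
      else "healthy",
      sprintf("%dx%d @ %.2f mm/px\n", nrow(x$image), ncol(x$image),
              x$pixel_spacing))
  invisible(x)
}
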