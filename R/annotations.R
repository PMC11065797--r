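#' Statistical reader profile
#'
#' A simulated radiologist. Detection of a nodule follows a logistic model in
#' `log2(views)`; ordinal quality/confidence/artifact scores are obtained by
#' thresholding latent scores that increase in `log2(views)` and in the
#' postprocessing indicator; segmentations of detected nodules are jittered
#' copies of the ground truth.
#'
#' The postprocessing effect (`processed_boost`) is tapered linearly from its
#' full value at 16 views to zero at 256 views, mirroring the emulated
#' observation that sparse and postprocessed images converge in quality as
#' views increase.
#'
#' @param reader_id identifier.
#' @param detection_slope,detection_intercept logistic coefficients on
#'   `log2(views)` for nodule detection (defaults fitted to a sensitivity
#'   rising from roughly 0.45 at 16 views to 1 at 128+ views).
#' @param processed_boost additive effect (latent-score units, must be
#'   `>= 0`) of postprocessing on detectability and scores, before tapering.
#' @param segmentation_jitter boundary/translation noise in mm for simulated
#'   segmentations.
#' @param false_mark_rate per-image probability of marking a nonexistent
#'   nodule on a healthy image.
#' @param score_thresholds list with elements `quality`, `confidence`
#'   (5 strictly increasing cut-points each, scores 1--6) and `artifact`
#'   (3 cut-points, scores 1--4).
#' @param effect additive per-reader shift on latent scores (reader
#'   leniency).
#' @return an object of class `reader_profile`.
#' @export
reader_profile <- function(reader_id,
                           detection_slope = 1.2,
                           detection_intercept = -5.0,
                           processed_boost = 1.4,
                           segmentation_jitter = 1.5,
                           false_mark_rate = 0.08,
                           score_thresholds = list(
                             quality = c(1.5, 2.5, 3.5, 4.5, 5.5),
                             confidence = c(1.5, 2.5, 3.5, 4.5, 5.5),
                             artifact = c(1.5, 2.5, 3.5)),
                           effect = 0) {
  stopifnot(processed_boost >= 0, detection_slope >= 0,
            all(diff(score_thresholds$quality) > 0),
            all(diff(score_thresholds$confidence) > 0),
            all(diff(score_thresholds$artifact) > 0))
  structure(list(reader_id = reader_id, detection_slope = detection_slope,
                 detection_intercept = detection_intercept,
                 processed_boost = processed_boost,
                 segmentation_jitter = segmentation_jitter,
                 false_mark_rate = false_mark_rate,
                 score_thresholds = score_thresholds, effect = effect),
            class = "reader_profile")
}

#' Default three-reader panel
#'
#' @param n_readers number of readers.
#' @param processed_boost,... passed to [reader_profile()].
#' @return list of `reader_profile`s with mildly different leniency.
#' @export
default_readers <- function(n_readers = 3L, processed_boost = 1.4, ...) {
  effects <- seq(-0.25, 0.25, length.out = max(n_readers, 2))[seq_len(n_readers)]
  lapply(seq_len(n_readers), function(i)
    reader_profile(sprintf("R%d", i), processed_boost = processed_boost,
                   effect = effects[i], ...))
}

# postprocessing effect taper: full at 16 views, zero at >= 256
boost_taper <- function(views) {
  pmax(0, pmin(1, (log2(256) - log2(views)) / (log2(256) - log2(16))))
}

latent_to_score <- function(latent, cuts) {
  1L + vapply(latent, function(x) sum(x > cuts), integer(1))
}

# jittered copy of the ground-truth nodule: translated by gaussian noise
# (sd = jitter mm) and radius-scaled; returns linear pixel indices
jitter_mask_idx <- function(mask, spacing, jitter_mm) {
  n <- nrow(mask)
  idx <- which(mask)
  if (!length(idx)) return(integer(0))
  cy <- mean((idx - 1) %% n + 1)
  cx <- mean((idx - 1) %/% n + 1)
  r <- sqrt(sum(mask) / pi)
  dy <- stats::rnorm(1, 0, jitter_mm / spacing)
  dx <- stats::rnorm(1, 0, jitter_mm / spacing)
  rs <- r * exp(stats::rnorm(1, 0, 0.08))
  d <- sqrt(outer((seq_len(n) - (cy + dy))^2, (seq_len(n) - (cx + dx))^2, "+"))
  which(d <= rs)
}

# a spurious disk mark placed away from the true nodule (if any)
random_mark_idx <- function(n, spacing, avoid_idx = integer(0)) {
  r <- stats::runif(1, 5, 8) / spacing / 2 * 10 / 10  # ~0.5-0.8 cm radius
  for (try in 1:50) {
    cy <- stats::runif(1, 0.25 * n, 0.75 * n)
    cx <- stats::runif(1, 0.2 * n, 0.8 * n)
    d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+"))
    idx <- which(d <= r)
    if (!length(intersect(idx, avoid_idx))) return(idx)
  }
  integer(0)
}

#' Simulate reader annotations for a cohort
#'
#' Produces one annotation record per reader x subject x view level x
#' processing arm: ordinal quality (1--6), confidence (1--6) and artifact
#' (1--4) scores, and a nodule segmentation (possibly empty). Detection is
#' drawn from the reader's logistic model; detected nodules are segmented as
#' jittered ground-truth masks; missed detections yield empty masks or, with
#' small probability, displaced masks with zero overlap; healthy images are
#' marked with probability `false_mark_rate`.
#'
#' @param cohort list of `phantom_slice`s.
#' @param view_series_per_subject named list of [make_view_series()] results,
#'   one per subject id, used to verify that every study condition has a
#'   reconstruction. May be `NULL` to skip the check (annotations are drawn
#'   from the statistical reader model, not from pixels).
#' @param readers list of [reader_profile()]s.
#' @param seed integer seed.
#' @param view_counts study view levels (512 is excluded by default, as in
#'   the emulated design).
#' @param noise_sd latent-score noise standard deviation; `0` makes scores
#'   deterministic functions of the design.
#' @return data frame of class `annotation_set`, one row per record, with a
#'   list-column `segmentation` of pixel-index vectors and an attribute
#'   `mask_dim`.
#' @export
simulate_annotations <- function(cohort, view_series_per_subject, readers,
                                 seed = 1L,
                                 view_counts = c(16L, 32L, 64L, 128L, 256L),
                                 noise_sd = 0.6) {
  if (!length(readers)) stop("reader list is empty")
  if (!is.null(view_series_per_subject)) {
    for (sl in cohort) {
      vs <- view_series_per_subject[[sl$subject_id]]
      if (is.null(vs) || !all(view_counts %in% vs$view_counts))
        stop("subject ", sl$subject_id,
             " lacks reconstructions for all study conditions")
    }
  }
  n <- nrow(cohort[[1]]$image)
  arms <- c("sparse", "processed")
  rows <- list(); segs <- list(); k <- 0L
  with_seed(seed, {
    for (rd in readers) {
      for (sl in cohort) {
        for (v in view_counts) {
          for (arm in arms) {
            k <- k + 1L
            proc <- arm == "processed"
            boost <- if (proc) rd$processed_boost * boost_taper(v) else 0
            lv <- log2(v)
            nz <- function() if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
            q_lat <- -2.1 + 0.82 * lv + boost + rd$effect + nz()
            c_lat <- -2.6 + 0.90 * lv + boost + rd$effect + nz()
            a_lat <- 6.2 - 0.55 * lv - 0.8 * boost - rd$effect + nz()
            quality <- latent_to_score(q_lat, rd$score_thresholds$quality)
            confid <- latent_to_score(c_lat, rd$score_thresholds$confidence)
            artifact <- latent_to_score(a_lat, rd$score_thresholds$artifact)
            artifact <- pmin(artifact, 4L)
            quality <- pmin(quality, 6L); confid <- pmin(confid, 6L)
            seg <- integer(0)
            if (sl$diseased) {
              eta <- rd$detection_intercept + rd$detection_slope * lv +
                0.5 * boost
              detected <- stats::runif(1) < stats::plogis(eta)
              truth_idx <- which(sl$nodule_mask)
              if (detected) {
                seg <- jitter_mask_idx(sl$nodule_mask, sl$pixel_spacing,
                                       rd$segmentation_jitter)
                if (!length(intersect(seg, truth_idx)))
                  seg <- truth_idx   # a detection always overlaps the truth
              } else if (stats::runif(1) < 0.25) {
                seg <- random_mark_idx(n, sl$pixel_spacing, truth_idx)
              }
            } else if (stats::runif(1) < rd$false_mark_rate) {
              seg <- random_mark_idx(n, sl$pixel_spacing)
            }
            rows[[k]] <- data.frame(reader_id = rd$reader_id,
                                    subject_id = sl$subject_id,
                                    view_count = v, arm = arm,
                                    quality = quality, confidence = confid,
                                    artifact = artifact,
                                    stringsAsFactors = FALSE)
            segs[[k]] <- seg
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out$segmentation <- segs
  attr(out, "mask_dim") <- c(n, n)
  class(out) <- c("annotation_set", class(out))
  out
}

#' Run-length encode a pixel-index mask
#'
#' Compact text representation ("start:length" pairs over the linearised
#' image) used when writing annotation sets to CSV.
#'
#' @param idx sorted integer vector of pixel indices.
#' @return a single string (empty for an empty mask).
#' @export
mask_to_rle <- function(idx) {
  if (!length(idx)) return("")
  idx <- sort(idx)
  breaks <- c(0, which(diff(idx) > 1), length(idx))
  paste(vapply(seq_len(length(breaks) - 1), function(i) {
    s <- idx[breaks[i] + 1]
    l <- breaks[i + 1] - breaks[i]
    paste0(s, ":", l)
  }, character(1)), collapse = ";")
}

#' Decode a run-length-encoded mask
#' @param rle string produced by [mask_to_rle()].
#' @return integer vector of pixel indices.
#' @export
rle_to_mask <- function(rle) {
  if (is.na(rle) || !nzchar(rle)) return(integer(0))
  parts <- strsplit(strsplit(rle, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  unlist(lapply(parts, function(p) {
    s <- as.integer(p[1]); l <- as.integer(p[2])
    seq.int(s, s + l - 1L)
  }))
}

#' Write an annotation set to CSV (masks as RLE strings)
#' @param annotations an `annotation_set`.
#' @param path output file.
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations
  df$segmentation <- vapply(df$segmentation, mask_to_rle, character(1))
  df$mask_nrow <- attr(annotations, "mask_dim")[1]
  df$mask_ncol <- attr(annotations, "mask_dim")[2]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an annotation set written by [write_annotations()]
#' @param path CSV file.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  md <- c(df$mask_nrow[1], df$mask_ncol[1])
  df$segmentation <- lapply(df$segmentation, rle_to_mask)
  df$mask_nrow <- NULL; df$mask_ncol <- NULL
  attr(df, "mask_dim") <- md
  class(df) <- c("annotation_set", class(df))
  df
}
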