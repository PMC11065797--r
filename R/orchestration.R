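#' Experiment configuration
#'
#' Bundles all stage configurations for the two experiments (model
#' assessment and reader study). The `desk` profile (default) runs end to
#' end on one CPU in minutes: 128x128 phantoms, a depth-2 U-Net, few
#' epochs. The `full` profile sets the published-scale values (512x512,
#' depth-4, 30 epochs) and is GPU-recommended.
#'
#' @param profile `"desk"` or `"full"` (published scale, GPU-recommended).
#' @param seed master seed; stage seeds are derived from it.
#' @param view_counts sparse view levels for the IQ path.
#' @param reader_view_counts view levels for the reader-study path (512 is
#'   excluded, as in the emulated design).
#' @param n_train_subjects,n_val_subjects,n_test_subjects,slices_per_subject
#'   training-path cohort shape.
#' @param processed_boost effect size of the simulated postprocessing on
#'   reader scores (0 = null model).
#' @param epochs training epochs for the desk profile.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "full"), seed = 1L,
                              view_counts = c(16L, 32L, 64L, 128L, 256L,
                                              512L),
                              reader_view_counts = c(16L, 32L, 64L, 128L,
                                                     256L),
                              n_train_subjects = 6L, n_val_subjects = 2L,
                              n_test_subjects = 3L, slices_per_subject = 4L,
                              processed_boost = 1.4, epochs = 5L) {
  profile <- match.arg(profile)
  size <- if (profile == "desk") 128L else 512L
  cohort <- cohort_config(n_subjects = 19L, diseased_fraction = 12 / 19,
                          image_size = size, seed = derive_seed(seed, "cohort"))
  unet <- if (profile == "desk") unet_config_toy(input_size = size)
          else unet_config_canonical()
  train <- train_config(max_epochs = if (profile == "desk") epochs else 30L,
                        seed = derive_seed(seed, "train"))
  structure(list(profile = profile, seed = as.integer(seed),
                 cohort = cohort, geometry = ct_geometry(),
                 window = window_config(), unet = unet, train = train,
                 view_counts = as.integer(view_counts),
                 reader_view_counts = as.integer(reader_view_counts),
                 n_train_subjects = as.integer(n_train_subjects),
                 n_val_subjects = as.integer(n_val_subjects),
                 n_test_subjects = as.integer(n_test_subjects),
                 slices_per_subject = as.integer(slices_per_subject),
                 processed_boost = processed_boost),
            class = "experiment_config")
}

# windowed view series for a list of slices
cohort_view_series <- function(slices, geometry, window, view_counts) {
  out <- lapply(slices, function(sl)
    window_view_series(make_view_series(sl$image, geometry, view_counts,
                                        subject_id = sl$subject_id),
                       window))
  names(out) <- vapply(slices, `[[`, character(1), "subject_id")
  out
}

#' Run the model-assessment experiment
#'
#' Generates a training-path cohort (several slices per subject), splits it
#' at subject level, builds windowed view series and residual pairs, trains
#' one model per requested view count, and evaluates MSE/SSIM of sparse and
#' postprocessed test images against the full-view reference.
#'
#' @param config an [experiment_config()].
#' @param view_counts view levels to train/evaluate (default: a desk subset).
#' @param verbose print progress.
#' @return list with `summaries` (data frame: view, arm, mean and 95% CI for
#'   MSE and SSIM), `records` (per-image metrics), `trainings` (per-view
#'   [train_model()] results), `split`.
#' @export
run_model_assessment <- function(config = experiment_config(),
                                 view_counts = c(16L, 64L, 256L),
                                 verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  n_sub <- config$n_train_subjects + config$n_val_subjects +
    config$n_test_subjects
  cc <- config$cohort
  cc$n_subjects <- n_sub
  ids <- sprintf("T%03d", seq_len(n_sub))
  split <- split_cohort(ids,
                        c(train = config$n_train_subjects / n_sub,
                          validation = config$n_val_subjects / n_sub,
                          test = config$n_test_subjects / n_sub),
                        seed = derive_seed(config$seed, "split"))
  slices <- unlist(lapply(ids, function(id)
    generate_slice_stack(id, diseased = TRUE, cc,
                         n_slices = config$slices_per_subject,
                         seed = derive_seed(cc$seed, id))),
    recursive = FALSE)
  if (verbose) message("reconstructing ", length(slices), " slices")
  series <- lapply(slices, function(sl)
    window_view_series(make_view_series(sl$image, config$geometry,
                                        view_counts,
                                        subject_id = sl$subject_id),
                       config$window))
  pairs_of <- function(sub_ids) {
    keep <- vapply(series, function(s) s$subject_id %in% sub_ids, logical(1))
    unlist(lapply(series[keep], series_residual_pairs,
                  view_counts = view_counts), recursive = FALSE)
  }
  by_view <- function(pairs) split(pairs, vapply(pairs, `[[`, integer(1),
                                                 "view_count"))
  tr <- by_view(pairs_of(split$train))
  va <- by_view(pairs_of(split$validation))
  te <- by_view(pairs_of(split$test))
  if (verbose) message("training ", length(tr), " view levels")
  trainings <- train_all_views(tr, va, config$unet, config$train,
                               verbose = verbose)
  records <- list(); k <- 0L
  for (v in names(te)) {
    model <- trainings[[v]]$model
    for (pair in te[[v]]) {
      full <- pair$sparse - pair$residual_label
      pred <- predict_residual(model, pair$sparse)
      post <- apply_residual_correction(pair$sparse, pred)
      k <- k + 1L
      records[[k]] <- data.frame(
        subject_id = pair$subject_id, view_count = pair$view_count,
        arm = c("sparse", "processed"),
        mse = c(mse(pair$sparse, full), mse(post, full)),
        ssim = c(ssim(pair$sparse, full), ssim(post, full)),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  summ <- do.call(rbind, lapply(split(records,
                                      records[, c("view_count", "arm")]),
    function(r) {
      sm <- summarize_iq(r$mse); ss <- summarize_iq(r$ssim)
      data.frame(view_count = r$view_count[1], arm = r$arm[1], n = sm$n,
                 mse_mean = sm$mean, mse_lo = sm$ci_low, mse_hi = sm$ci_high,
                 ssim_mean = ss$mean, ssim_lo = ss$ci_low,
                 ssim_hi = ss$ci_high, stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(summaries = summ[order(summ$view_count, summ$arm), ],
       records = records, trainings = trainings, split = split,
       manifest = run_manifest(config, view_counts))
}

# reproducibility record emitted with every experiment report
run_manifest <- function(config, view_counts) {
  list(seed = config$seed, profile = config$profile,
       view_counts = view_counts,
       config_digest = sum(utf8ToInt(paste(deparse(config),
                                           collapse = ""))),
       package_version = as.character(utils::packageVersion("sparsect")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the reader-study experiment
#'
#' Generates the 19-subject reader cohort (12 diseased, 7 healthy), verifies
#' that reconstructions exist for every study condition, simulates the
#' reader panel, and analyses the annotations: pooled condition means,
#' per-condition diagnostic metrics, and per-view clustered Wilcoxon
#' comparisons of the processed versus sparse arms.
#'
#' @param config an [experiment_config()].
#' @param readers optional list of [reader_profile()]s (default: three
#'   readers with the config's `processed_boost`).
#' @param with_series build the (windowed) view series for the cohort; set
#'   `FALSE` to skip reconstruction in statistical simulations.
#' @return list with `annotations`, `score_means`, `diagnostics` (per view x
#'   arm), `tests` (clustered Wilcoxon p-values), `cohort`.
#' @export
run_reader_study <- function(config = experiment_config(), readers = NULL,
                             with_series = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort)
  series <- if (with_series)
    cohort_view_series(cohort, config$geometry, config$window,
                       config$reader_view_counts)
  else NULL
  if (is.null(readers))
    readers <- default_readers(3L, processed_boost = config$processed_boost)
  ann <- simulate_annotations(cohort, series, readers,
                              seed = derive_seed(config$seed, "annotate"),
                              view_counts = config$reader_view_counts)
  cls <- classify_annotations(ann, cohort)
  ann$label <- cls$label
  ann$dsc <- cls$dsc
  diag_rows <- lapply(split(cls, cls[, c("view_count", "arm")]), function(r) {
    dm <- diagnostic_metrics(r)
    data.frame(view_count = r$view_count[1], arm = r$arm[1], n = nrow(r),
               sensitivity = dm$sensitivity, specificity = dm$specificity,
               f1 = dm$f1, npv = dm$npv, stringsAsFactors = FALSE)
  })
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  tests <- compare_arms(ann,
                        measures = c("quality", "confidence", "artifact"))
  list(annotations = ann,
       score_means = summarize_scores(ann),
       diagnostics = diagnostics[order(diagnostics$view_count,
                                       diagnostics$arm), ],
       tests = tests, cohort = cohort,
       manifest = run_manifest(config, config$reader_view_counts))
}
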