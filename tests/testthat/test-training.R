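test_that("the learning-rate schedule matches its closed form", {
  tc <- train_config()
  expect_equal(lr_at_epoch(0, tc), 0.001)
  expect_equal(lr_at_epoch(1, tc), 0.001 * exp(-0.1), tolerance = 1e-12)
  expect_equal(lr_at_epoch(10, tc), 0.001 * exp(-1), tolerance = 1e-12)
  n <- 0:29
  expect_equal(lr_at_epoch(n, tc), 0.001 * exp(-0.1 * n), tolerance = 1e-12)
  expect_true(all(diff(lr_at_epoch(n, tc)) < 0))
  expect_error(lr_at_epoch(-1, tc), ">= 0")
})

test_that("early stopping and checkpoint selection follow the rules", {
  pairs <- toy_pairs(4, size = 16L, seed = 1L)
  val <- toy_pairs(2, size = 16L, seed = 2L, subject_prefix = "V")
  cfg <- unet_config(input_size = 16L, depth = 1L, widths = 2L,
                     bottleneck = 2L, seed = 5L)
  # scripted validation losses isolate the stopping mechanism
  script <- c(0.5, 0.4, 0.4, 0.4, 0.4, 0.4)
  i <- 0
  local_mocked_bindings(
    eval_loss = function(...) { i <<- i + 1; script[i] },
    .package = "sparsect")
  m <- build_model(cfg)
  res <- train_model(m, pairs, val,
                     train_config(max_epochs = 10L, batch_size = 4L,
                                  patience = 1L, seed = 3L))
  expect_equal(res$best_epoch, 2L)
  expect_equal(nrow(res$history), 3L)       # stops at epoch 3
  expect_true(res$stopped_early)

  # strictly improving validation -> runs to the end, best = last
  script <- seq(0.6, 0.1, length.out = 6)
  i <- 0
  res2 <- train_model(build_model(cfg), pairs, val,
                      train_config(max_epochs = 6L, batch_size = 4L,
                                   patience = 2L, seed = 3L))
  expect_false(res2$stopped_early)
  expect_equal(res2$best_epoch, 6L)
  expect_equal(res2$history$lr, 0.001 * exp(-0.1 * (0:5)), tolerance = 1e-12)
  expect_equal(min(res2$history$val_loss),
               res2$history$val_loss[res2$best_epoch])
})

test_that("training rejects invalid inputs", {
  pairs <- toy_pairs(3, size = 16L, seed = 3L)
  cfg <- unet_config(input_size = 16L, depth = 1L, widths = 2L,
                     bottleneck = 2L, seed = 5L)
  m <- build_model(cfg)
  expect_error(train_model(m, list(), pairs), "empty training")
  expect_error(train_model(m, pairs, list()), "empty validation")
  expect_error(train_model(m, pairs, pairs), "share subjects")
})

test_that("train_all_views yields independent per-view models", {
  mkv <- function(v, seed) {
    p <- toy_pairs(3, size = 16L, seed = seed)
    lapply(p, function(q) { q$view_count <- v; q })
  }
  tr <- list("32" = mkv(32L, 10L), "64" = mkv(64L, 11L))
  va <- list("32" = mkv(32L, 12L), "64" = mkv(64L, 13L))
  va <- lapply(va, function(l) lapply(l, function(q) {
    q$subject_id <- paste0("V", q$subject_id); q }))
  cfg <- unet_config(input_size = 16L, depth = 1L, widths = 2L,
                     bottleneck = 2L, seed = 5L)
  res <- train_all_views(tr, va, cfg,
                         train_config(max_epochs = 1L, batch_size = 3L,
                                      seed = 2L))
  expect_named(res, c("32", "64"))
  expect_false(identical(res[["32"]]$model$params,
                         res[["64"]]$model$params))

  one <- train_all_views(tr["32"], va, cfg,
                         train_config(max_epochs = 1L, batch_size = 3L,
                                      seed = 2L))
  expect_named(one, "32")
  expect_error(train_all_views(tr, va["32"], cfg), "missing")

  # per-view runs are reproducible
  res2 <- train_all_views(tr, va, cfg,
                          train_config(max_epochs = 1L, batch_size = 3L,
                                       seed = 2L))
  expect_equal(res[["32"]]$model$params, res2[["32"]]$model$params)
})

test_that("desk-scale training reduces MSE at most view levels", {
  # scaled-down version of the multi-view efficacy property: 64x64 slices,
  # three view levels, a few epochs; at least 2 of 3 levels must improve
  cfg <- cohort_config(image_size = 64L, pixel_spacing = 1.4, seed = 41L)
  w <- window_config()
  views <- c(32L, 64L, 128L)
  n_sub <- 12L
  pairs <- list()
  for (s in seq_len(n_sub)) {
    id <- sprintf("E%02d", s)
    ph <- generate_phantom(id, TRUE, cfg, seed = 4100L + s)
    vs <- window_view_series(make_view_series(ph$image, view_counts = views,
                                              subject_id = id), w)
    pairs <- c(pairs, series_residual_pairs(vs, views))
  }
  subj <- vapply(pairs, `[[`, character(1), "subject_id")
  vw <- vapply(pairs, `[[`, integer(1), "view_count")
  train_ids <- sprintf("E%02d", 1:8)
  val_ids <- sprintf("E%02d", 9:10)
  test_ids <- sprintf("E%02d", 11:12)
  improved <- logical(0)
  for (v in views) {
    tr <- pairs[vw == v & subj %in% train_ids]
    va <- pairs[vw == v & subj %in% val_ids]
    te <- pairs[vw == v & subj %in% test_ids]
    m <- build_model(unet_config_toy(input_size = 64L, base = 8L,
                                     seed = 100L + v))
    res <- train_model(m, tr, va,
                       train_config(max_epochs = 5L, batch_size = 4L,
                                    patience = 5L, seed = 7L))
    sp <- vapply(te, function(p)
      mse(p$sparse, p$sparse - p$residual_label), numeric(1))
    po <- vapply(te, function(p) {
      post <- apply_residual_correction(
        p$sparse, predict_residual(res$model, p$sparse))
      mse(post, p$sparse - p$residual_label)
    }, numeric(1))
    improved <- c(improved, mean(po) < mean(sp))
  }
  expect_gte(sum(improved), 2L)
})
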