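small_cohort <- function(n_sub = 19L, frac = 12 / 19, seed = 31L)
  generate_cohort(cohort_config(n_subjects = n_sub, diseased_fraction = frac,
                                image_size = 64L, pixel_spacing = 1.4,
                                seed = seed))

test_that("the full design yields 570 records, 190 per reader", {
  cohort <- small_cohort()
  readers <- default_readers(3L)
  ann <- simulate_annotations(cohort, NULL, readers, seed = 5L)
  expect_equal(nrow(ann), 570L)
  expect_equal(unname(table(ann$reader_id)), rep(190L, 3L),
               ignore_attr = TRUE)
  # one record per reader x subject x view x arm
  expect_equal(nrow(unique(ann[, c("reader_id", "subject_id", "view_count",
                                   "arm")])), 570L)
  expect_true(all(ann$quality %in% 1:6))
  expect_true(all(ann$confidence %in% 1:6))
  expect_true(all(ann$artifact %in% 1:4))
  expect_error(simulate_annotations(cohort, NULL, list(), seed = 1L),
               "empty")
})

test_that("annotation simulation is deterministic in the seed", {
  cohort <- small_cohort(5L, 3 / 5)
  readers <- default_readers(2L)
  a <- simulate_annotations(cohort, NULL, readers, seed = 11L)
  b <- simulate_annotations(cohort, NULL, readers, seed = 11L)
  expect_identical(a, b)
  c <- simulate_annotations(cohort, NULL, readers, seed = 12L)
  expect_false(identical(a$quality, c$quality))
})

test_that("null readers score both arms identically", {
  cohort <- small_cohort(6L, 0.5)
  readers <- default_readers(2L, processed_boost = 0)
  ann <- simulate_annotations(cohort, NULL, readers, seed = 3L, noise_sd = 0)
  sp <- ann[ann$arm == "sparse", ]
  pr <- ann[ann$arm == "processed", ]
  key <- function(d) order(d$reader_id, d$subject_id, d$view_count)
  sp <- sp[key(sp), ]; pr <- pr[key(pr), ]
  expect_equal(sp$quality, pr$quality)
  expect_equal(sp$confidence, pr$confidence)
  expect_equal(sp$artifact, pr$artifact)
})

test_that("detection rate increases with views under a positive slope", {
  # Monte-Carlo over the logistic detection model: aggregate detections at
  # 16 vs 256 views across repeated small cohorts (scaled-down version of
  # the 1,000-cohort check; direction is what matters)
  cohort <- small_cohort(6L, 1)
  readers <- list(reader_profile("R1", detection_slope = 2))
  det16 <- det256 <- 0
  for (s in 1:60) {
    ann <- simulate_annotations(cohort, NULL, readers, seed = 1000L + s)
    marked <- vapply(ann$segmentation, length, integer(1)) > 0
    det16 <- det16 + sum(marked[ann$view_count == 16])
    det256 <- det256 + sum(marked[ann$view_count == 256])
  }
  expect_gte(det256, det16)
})

test_that("mean quality is nondecreasing in views for both arms", {
  cohort <- small_cohort()
  ann <- simulate_annotations(cohort, NULL, default_readers(3L), seed = 21L)
  for (a in c("sparse", "processed")) {
    m <- tapply(ann$quality[ann$arm == a], ann$view_count[ann$arm == a],
                mean)
    expect_true(all(diff(m[order(as.integer(names(m)))]) >= 0))
  }
})

test_that("series completeness is enforced when view series are supplied", {
  cohort <- small_cohort(2L, 0.5)
  vs <- lapply(cohort, function(sl)
    make_view_series(sl$image, view_counts = c(16L, 64L),
                     subject_id = sl$subject_id))
  names(vs) <- vapply(cohort, `[[`, character(1), "subject_id")
  expect_error(simulate_annotations(cohort, vs, default_readers(1L),
                                    seed = 1L),
               "lacks reconstructions")
})

test_that("RLE mask encoding round-trips through CSV", {
  cohort <- small_cohort(4L, 0.5)
  ann <- simulate_annotations(cohort, NULL, default_readers(2L), seed = 9L)
  idx <- which(vapply(ann$segmentation, length, integer(1)) > 0)
  expect_gt(length(idx), 0)
  for (i in head(idx, 5))
    expect_identical(rle_to_mask(mask_to_rle(ann$segmentation[[i]])),
                     sort(ann$segmentation[[i]]))
  expect_identical(rle_to_mask(mask_to_rle(integer(0))), integer(0))

  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$quality, ann$quality)
  expect_equal(lapply(back$segmentation, sort),
               lapply(ann$segmentation, sort))
  expect_equal(attr(back, "mask_dim"), attr(ann, "mask_dim"))
})
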