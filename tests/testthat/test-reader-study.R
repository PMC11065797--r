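rand_mask <- function(n = 16, p = 0.2) matrix(runif(n * n) < p, n, n)

test_that("dice matches pixel counting and the zero rule", {
  m1 <- matrix(FALSE, 20, 20); m1[1:10, 1:10] <- TRUE   # |A| = 100
  m2 <- matrix(FALSE, 20, 20); m2[7:11, 1:10] <- TRUE   # |B| = 50, overlap 40
  expect_equal(dice(m1, m2), 2 * 40 / 150)

  expect_equal(dice(m1, m1), 1)
  disjoint <- matrix(FALSE, 20, 20); disjoint[15:18, 15:18] <- TRUE
  expect_equal(dice(m1, disjoint), 0)
  expect_equal(dice(m1, matrix(FALSE, 20, 20)), 0)
  expect_equal(dice(matrix(FALSE, 20, 20), matrix(FALSE, 20, 20)), 0)
  expect_error(dice(m1, matrix(FALSE, 2, 2)), "shape")

  set.seed(8)
  for (i in 1:100) {
    a <- rand_mask(); b <- rand_mask()
    d <- dice(a, b)
    expect_equal(d, bf_dice(a, b), tolerance = 1e-12)
    expect_equal(d, dice(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    if (d == 1) expect_identical(a, b)
  }
})

test_that("classify_detection is exhaustive and follows the FN rule", {
  cfg <- cohort_config(n_subjects = 2L, image_size = 64L,
                       pixel_spacing = 1.4, seed = 13L)
  diseased <- generate_phantom("D1", TRUE, cfg, seed = 13L)
  healthy <- generate_phantom("H1", FALSE, cfg, seed = 14L)
  rec <- function(id, seg) list(reader_id = "R1", subject_id = id,
                                view_count = 64L, arm = "sparse",
                                segmentation = seg)

  expect_equal(classify_detection(rec("H1", integer(0)), healthy)$label, "TN")
  expect_equal(classify_detection(rec("H1", 1:40), healthy)$label, "FP")

  truth_idx <- which(diseased$nodule_mask)
  out <- classify_detection(rec("D1", truth_idx), diseased)
  expect_equal(out$label, "TP")
  expect_equal(out$dsc, 1)

  displaced <- setdiff(1:200, truth_idx)[1:50]
  expect_equal(classify_detection(rec("D1", displaced), diseased)$label, "FN")
  expect_equal(classify_detection(rec("D1", integer(0)), diseased)$label,
               "FN")

  partial <- c(truth_idx[1:20], displaced[1:10])
  o <- classify_detection(rec("D1", partial), diseased)
  expect_equal(o$label, "TP")
  expect_gt(o$dsc, 0); expect_lte(o$dsc, 1)

  expect_error(classify_detection(rec("D1", truth_idx), healthy),
               "different subjects")
})

test_that("classification over a simulated cohort partitions correctly", {
  cohort <- generate_cohort(cohort_config(n_subjects = 8L,
                                          diseased_fraction = 0.5,
                                          image_size = 64L,
                                          pixel_spacing = 1.4, seed = 17L))
  ann <- simulate_annotations(cohort, NULL, default_readers(2L), seed = 18L)
  cls <- classify_annotations(ann, cohort)
  expect_equal(nrow(cls), nrow(ann))
  status <- setNames(vapply(cohort, `[[`, logical(1), "diseased"),
                     vapply(cohort, `[[`, character(1), "subject_id"))
  dis <- status[cls$subject_id]
  expect_true(all(cls$label[dis] %in% c("TP", "FN")))
  expect_true(all(cls$label[!dis] %in% c("FP", "TN")))
  expect_true(all(!is.na(cls$dsc[cls$label == "TP"])))
  expect_true(all(is.na(cls$dsc[cls$label != "TP"])))
})

test_that("diagnostic_metrics matches the closed formulas and recounts", {
  # counts consistent with the 57-record design (36 diseased + 21 healthy)
  d <- diagnostic_metrics(c(rep("TP", 34), rep("FN", 2), rep("FP", 2),
                            rep("TN", 19)))
  expect_equal(round(unname(d$sensitivity), 2), 0.94)
  expect_equal(round(unname(d$specificity), 2), 0.90)
  expect_equal(unname(d$f1), 2 * 34 / (2 * 34 + 2 + 2))
  expect_equal(unname(d$npv), 19 / 21)

  allpos <- diagnostic_metrics(rep("TP", 5))
  expect_equal(unname(allpos$sensitivity), 1)
  expect_true(is.na(allpos$specificity))
  expect_true(is.na(allpos$npv))

  set.seed(9)
  for (i in 1:50) {
    labs <- sample(c("TP", "FP", "FN", "TN"), 30, replace = TRUE)
    d <- diagnostic_metrics(labs)
    expect_equal(unname(d$counts),
                 unname(c(sum(labs == "TP"), sum(labs == "FP"),
                          sum(labs == "FN"), sum(labs == "TN"))))
    expect_equal(sum(d$counts), 30)
    if (!is.na(d$sensitivity))
      expect_equal(unname(d$sensitivity),
                   sum(labs == "TP") / sum(labs %in% c("TP", "FN")))
  }
  expect_error(diagnostic_metrics(character(0)), "no outcomes")
})

test_that("clustered_wilcoxon reduces to the classical test for singletons", {
  set.seed(10)
  for (i in 1:20) {
    d <- round(rnorm(25, 0.3), 2)   # ties and zeros on purpose
    ref <- bf_signed_rank(d, "greater")
    out <- clustered_wilcoxon(d, cluster = seq_along(d))
    expect_equal(out$t, ref$t, tolerance = 1e-6)
    expect_equal(out$statistic, ref$z, tolerance = 1e-6)
    expect_equal(out$p_value, ref$p, tolerance = 1e-6)
  }
})

test_that("clustered_wilcoxon handles degenerate and invalid input", {
  z <- clustered_wilcoxon(rep(0, 10), cluster = rep(1:5, 2))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  expect_error(clustered_wilcoxon(1:4, cluster = rep(1, 4)), "2 clusters")
  expect_error(clustered_wilcoxon(1:4, cluster = 1:3), "length")
  two <- clustered_wilcoxon(c(1, 2, -1, 3), c(0, 0, 0, 0),
                            cluster = c(1, 1, 2, 2),
                            alternative = "two.sided")
  expect_gte(two$p_value, 0); expect_lte(two$p_value, 1)
})

test_that("analytic p agrees with a within-cluster sign-flip permutation", {
  # study-sized sample: 19 clusters x 3 readers
  set.seed(11)
  cl <- rep(1:19, each = 3)
  d <- rnorm(57, 0.25, 1) + rep(rnorm(19, 0, 0.5), each = 3)
  ana <- clustered_wilcoxon(d, cluster = cl)
  r <- rank(abs(d)); sr <- sign(d) * r
  tobs <- sum(sr)
  nperm <- 4000
  hits <- 0
  for (b in seq_len(nperm)) {
    flips <- rep(sample(c(-1, 1), 19, replace = TRUE), each = 3)
    if (sum(sr * flips) >= tobs) hits <- hits + 1
  }
  expect_lt(abs(ana$p_value - hits / nperm), 0.02)
})

test_that("power grows with the effect size", {
  set.seed(12)
  rej <- sapply(c(0, 0.6), function(shift) {
    mean(replicate(150, {
      cl <- rep(1:19, each = 3)
      d <- rnorm(57, shift, 1) + rep(rnorm(19, 0, 0.3), each = 3)
      clustered_wilcoxon(d, cluster = cl)$p_value < 0.05
    }))
  })
  expect_gt(rej[2], rej[1])
})

test_that("summarize_scores pools conditions as designed", {
  cohort <- generate_cohort(cohort_config(n_subjects = 19L,
                                          diseased_fraction = 12 / 19,
                                          image_size = 64L,
                                          pixel_spacing = 1.4, seed = 23L))
  ann <- simulate_annotations(cohort, NULL, default_readers(3L), seed = 24L)
  sm <- summarize_scores(ann)
  expect_true(all(sm$n == 57L))            # 3 readers x 19 subjects
  expect_equal(nrow(sm), 10L)              # 5 views x 2 arms

  flat <- ann; flat$quality <- 4L
  expect_true(all(summarize_scores(flat)$quality == 4))
  u <- ann; u$quality <- rep_len(1:6, nrow(u))
  expect_equal(mean(summarize_scores(u)$quality), 3.5, tolerance = 0.01)
})
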