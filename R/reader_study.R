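#' Dice similarity coefficient with the empty/no-overlap zero rule
#'
#' `2|A ∩ B| / (|A| + |B|)`, defined as 0 when either mask is empty or
#' the masks do not overlap.
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("shape mismatch")
  a <- sum(mask_a); b <- sum(mask_b)
  if (a == 0 || b == 0) return(0)
  inter <- sum(mask_a & mask_b)
  if (inter == 0) return(0)
  2 * inter / (a + b)
}

# dice on pixel-index vectors (same zero rule)
dice_idx <- function(idx_a, idx_b) {
  if (!length(idx_a) || !length(idx_b)) return(0)
  inter <- length(intersect(idx_a, idx_b))
  if (inter == 0) return(0)
  2 * inter / (length(idx_a) + length(idx_b))
}

#' Classify one reader mark against the ground truth
#'
#' Diseased subject: a mark overlapping the true nodule is a true positive
#' (with its Dice coefficient); an empty mark, or a displaced mark with zero
#' overlap, is a false negative. Healthy subject: any mark is a false
#' positive; an empty mark is a true negative. A displaced mark on a diseased
#' image counts as FN only (not FN + FP).
#'
#' @param record one row of an `annotation_set` (data frame with a
#'   `segmentation` list-column), or a list with fields `reader_id`,
#'   `subject_id`, `view_count`, `arm`, `segmentation` (pixel indices).
#' @param truth the matching `phantom_slice`.
#' @return an object of class `detection_outcome`: list with `reader_id`,
#'   `subject_id`, `view_count`, `arm`, `label` in `{"TP","FP","FN","TN"}`
#'   and `dsc` (`NA` unless TP).
#' @export
classify_detection <- function(record, truth) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    seg <- record$segmentation[[1]]
    rec <- as.list(record[1, c("reader_id", "subject_id", "view_count", "arm")])
  } else {
    seg <- record$segmentation
    rec <- record
  }
  if (!identical(as.character(rec$subject_id),
                 as.character(truth$subject_id)))
    stop("record and truth refer to different subjects")
  truth_idx <- which(truth$nodule_mask)
  if (truth$diseased) {
    overlap <- length(intersect(seg, truth_idx))
    if (length(seg) && overlap > 0) {
      label <- "TP"
      dsc <- 2 * overlap / (length(seg) + length(truth_idx))
    } else {
      label <- "FN"; dsc <- NA_real_
    }
  } else {
    label <- if (length(seg)) "FP" else "TN"
    dsc <- NA_real_
  }
  structure(list(reader_id = rec$reader_id, subject_id = rec$subject_id,
                 view_count = rec$view_count, arm = rec$arm, label = label,
                 dsc = dsc),
            class = "detection_outcome")
}

#' Classify every record of an annotation set
#'
#' @param annotations an `annotation_set`.
#' @param cohort the list of `phantom_slice`s the annotations refer to.
#' @return data frame with one row per record: ids, condition, `label`,
#'   `dsc`.
#' @export
classify_annotations <- function(annotations, cohort) {
  names(cohort) <- vapply(cohort, `[[`, character(1), "subject_id")
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    o <- classify_detection(annotations[i, ],
                            cohort[[annotations$subject_id[i]]])
    data.frame(reader_id = o$reader_id, subject_id = o$subject_id,
               view_count = o$view_count, arm = o$arm, label = o$label,
               dsc = o$dsc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diagnostic summary from detection outcomes
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1
#' `2TP/(2TP+FP+FN)`, NPV `TN/(TN+FN)`. Undefined ratios (zero denominator)
#' are reported as `NA`, not 0.
#'
#' @param outcomes data frame with a `label` column (as from
#'   [classify_annotations()]) or a character vector of labels.
#' @return an object of class `diagnostic_summary`: list with the four
#'   metrics and the `counts`.
#' @export
diagnostic_metrics <- function(outcomes) {
  labels <- if (is.data.frame(outcomes)) outcomes$label else outcomes
  if (!length(labels)) stop("no outcomes")
  counts <- c(tp = sum(labels == "TP"), fp = sum(labels == "FP"),
              fn = sum(labels == "FN"), tn = sum(labels == "TN"))
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = div(counts["tp"], counts["tp"] + counts["fn"]),
    specificity = div(counts["tn"], counts["tn"] + counts["fp"]),
    f1 = div(2 * counts["tp"], 2 * counts["tp"] + counts["fp"] + counts["fn"]),
    npv = div(counts["tn"], counts["tn"] + counts["fn"]),
    counts = counts), class = "diagnostic_summary")
}

#' Clustered Wilcoxon signed-rank test
#'
#' Signed-rank test for paired differences with correlated observations
#' inside clusters (here: the readers rating the same subject), using the
#' cluster-robust variance of Rosner, Glynn and Lee: zero differences are
#' dropped, absolute differences are ranked across all remaining
#' observations (average ranks for ties), the statistic is the sum of signed
#' ranks `T`, and `Var(T)` is estimated by the sum of squared within-cluster
#' signed-rank sums. The p-value uses the asymptotic normal approximation.
#' With singleton clusters this reduces exactly to the classical signed-rank
#' normal approximation.
#'
#' @param x,y paired observations (test asks whether `x` exceeds `y`), or
#'   `x` a vector of paired differences and `y` missing.
#' @param cluster cluster key, same length as `x`.
#' @param alternative `"greater"` (default, one-sided superiority),
#'   `"less"`, or `"two.sided"`.
#' @return object of class `clustered_wilcoxon`: list with `statistic`
#'   (standardized Z), `t` (signed-rank sum), `p_value`, `n_clusters`,
#'   `n_nonzero`, `degenerate` (TRUE when all differences are zero).
#' @export
clustered_wilcoxon <- function(x, y = NULL, cluster,
                               alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) != length(cluster)) stop("cluster length mismatch")
  if (anyNA(d) || anyNA(cluster)) stop("missing values not allowed")
  if (length(unique(cluster)) < 2) stop("need at least 2 clusters")
  keep <- d != 0
  if (!any(keep)) {
    return(structure(list(statistic = 0, t = 0, p_value = 1,
                          n_clusters = length(unique(cluster)), n_nonzero = 0,
                          degenerate = TRUE),
                     class = "clustered_wilcoxon"))
  }
  d <- d[keep]; cl <- cluster[keep]
  r <- rank(abs(d))
  sr <- sign(d) * r
  tsum <- sum(sr)
  cl_sums <- tapply(sr, cl, sum)
  v <- sum(cl_sums^2)
  z <- tsum / sqrt(v)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(statistic = z, t = tsum, p_value = p,
                 n_clusters = length(unique(cluster)),
                 n_nonzero = length(d), degenerate = FALSE),
            class = "clustered_wilcoxon")
}

#' @export
print.clustered_wilcoxon <- function(x, ...) {
  cat(sprintf("clustered Wilcoxon signed-rank: T = %g, Z = %.4g, p = %.4g%s\n",
              x$t, x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: all differences zero)" else ""))
  invisible(x)
}

#' Pooled condition means of reader scores
#'
#' Means of quality, confidence, artifact scores and (optionally) Dice
#' coefficients per (view count, arm) condition, pooled over readers and
#' subjects.
#'
#' @param records an `annotation_set`, optionally augmented with columns
#'   `label` and `dsc` (see [classify_annotations()]).
#' @param dsc_mode how to average Dice values when present:
#'   `"tp_zero"` counts non-TP diseased records as zeros (default),
#'   `"tp_only"` averages over true positives only.
#' @return data frame with one row per condition and columns `view_count`,
#'   `arm`, `n`, `quality`, `confidence`, `artifact`, and `dsc` when
#'   available.
#' @export
summarize_scores <- function(records, dsc_mode = c("tp_zero", "tp_only")) {
  dsc_mode <- match.arg(dsc_mode)
  conds <- unique(records[, c("view_count", "arm")])
  conds <- conds[order(conds$view_count, conds$arm), ]
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- records$view_count == conds$view_count[i] &
      records$arm == conds$arm[i]
    r <- records[sel, ]
    out <- data.frame(view_count = conds$view_count[i], arm = conds$arm[i],
                      n = nrow(r), quality = mean(r$quality),
                      confidence = mean(r$confidence),
                      artifact = mean(r$artifact), stringsAsFactors = FALSE)
    if ("dsc" %in% names(r) && "label" %in% names(r)) {
      if (dsc_mode == "tp_zero") {
        v <- ifelse(r$label == "TP", r$dsc, 0)
        v <- v[r$label %in% c("TP", "FN")]   # diseased records only
      } else {
        v <- r$dsc[r$label == "TP"]
      }
      out$dsc <- if (length(v)) mean(v) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Per-view clustered Wilcoxon comparisons of the two arms
#'
#' For each view level, pairs the processed and sparse records of every
#' (reader, subject) and tests processed > sparse with
#' [clustered_wilcoxon()], clustering by subject.
#'
#' @param records an `annotation_set` (optionally with `dsc`).
#' @param measures columns to test.
#' @param cluster_by `"subject"` (default) or `"reader"`.
#' @param alpha significance threshold used for the `significant` flag.
#' @return data frame with `view_count`, `measure`, `p_value`,
#'   `significant`.
#' @export
compare_arms <- function(records,
                         measures = c("quality", "confidence", "artifact"),
                         cluster_by = c("subject", "reader"), alpha = 0.05) {
  cluster_by <- match.arg(cluster_by)
  views <- sort(unique(records$view_count))
  rows <- list(); k <- 0L
  for (v in views) {
    r <- records[records$view_count == v, ]
    p <- r[r$arm == "processed", ]
    s <- r[r$arm == "sparse", ]
    key <- function(df) paste(df$reader_id, df$subject_id)
    m <- match(key(p), key(s))
    if (anyNA(m)) stop("incomplete pairs at view ", v)
    s <- s[m, ]
    cl <- if (cluster_by == "subject") p$subject_id else p$reader_id
    for (meas in measures) {
      k <- k + 1L
      # artifact severity improves downward: test sparse > processed
      tst <- if (meas == "artifact")
        clustered_wilcoxon(s[[meas]], p[[meas]], cluster = cl)
      else clustered_wilcoxon(p[[meas]], s[[meas]], cluster = cl)
      rows[[k]] <- data.frame(view_count = v, measure = meas,
                              p_value = tst$p_value,
                              significant = tst$p_value < alpha,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
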