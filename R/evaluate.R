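## Evaluation: confusion counts, segmentation and classification metrics,
## sequential leave-eleven-out cross-validation, and the paired-t / exact
## Wilcoxon comparison between classifier arms.

#' Confusion counts
#'
#' Elementwise comparison of predictions against truth. The positive class
#' is foreground (segmentation masks) or fractured (labels).
#'
#' @param pred,truth 0/1 matrices or label vectors of equal length.
#' @param positive value treated as positive (default 1).
#' @return list of class `"confusion"` with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth, positive = 1L) {
  p <- as.vector(pred) == positive
  t_ <- as.vector(truth) == positive
  if (length(p) != length(t_)) stop("pred and truth sizes differ", call. = FALSE)
  structure(list(TP = sum(p & t_), TN = sum(!p & !t_),
                 FP = sum(p & !t_), FN = sum(!p & t_)),
            class = "confusion")
}

ratio_pct <- function(num, den) {
  if (den == 0) {
    structure(0, degenerate = TRUE)
  } else 100 * num / den
}

#' Segmentation metrics
#'
#' Accuracy, sensitivity, Dice similarity coefficient and Jaccard
#' coefficient as percentages. A zero denominator yields 0 with a
#' `degenerate` attribute (and the result carries `degenerate = TRUE`)
#' rather than an error, so batch evaluation survives empty predictions.
#'
#' @param counts a [confusion()] object.
#' @return list with `accuracy`, `sensitivity`, `dsc`, `jaccard` (each in
#'   `[0, 100]`) and logical `degenerate`.
#' @export
seg_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion"))
  with(counts, {
    out <- list(
      accuracy = ratio_pct(TP + TN, TP + TN + FP + FN),
      sensitivity = ratio_pct(TP, TP + FN),
      dsc = ratio_pct(2 * TP, 2 * TP + FP + FN),
      jaccard = ratio_pct(TP, TP + FP + FN))
    out$degenerate <- any(vapply(out, function(v) isTRUE(attr(v, "degenerate")), logical(1)))
    out
  })
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F-measure (harmonic mean of precision
#' and recall) as percentages, with the same zero-denominator convention as
#' [seg_metrics()].
#'
#' @inheritParams seg_metrics
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `degenerate`.
#' @export
cls_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion"))
  with(counts, {
    prec <- ratio_pct(TP, TP + FP)
    rec <- ratio_pct(TP, TP + FN)
    f1 <- if (prec + rec == 0) structure(0, degenerate = TRUE) else {
      2 * prec * rec / (prec + rec)
    }
    out <- list(accuracy = ratio_pct(TP + TN, TP + TN + FP + FN),
                precision = prec, recall = rec, f1 = f1)
    out$degenerate <- any(vapply(out, function(v) isTRUE(attr(v, "degenerate")), logical(1)))
    out
  })
}

#' Dice similarity between two masks
#' @param a,b 0/1 matrices of the same shape.
#' @return Dice coefficient in percent.
#' @export
dice <- function(a, b) seg_metrics(confusion(as_mask(a), as_mask(b)))$dsc

#' Sequential fold assignment
#'
#' Splits `1..n` sequentially into disjoint test folds of `fold_size`; when
#' `fold_size` does not divide `n`, the final fold holds the (smaller)
#' remainder, so 63 cases at fold size 11 give folds of 11, 11, 11, 11, 11
#' and 8.
#'
#' @param n number of cases (must exceed `fold_size`).
#' @param fold_size nominal fold size.
#' @return list of integer index vectors, one per fold.
#' @export
sequential_folds <- function(n, fold_size = 11L) {
  if (n < fold_size + 1) stop(sprintf("need more than %d cases", fold_size), call. = FALSE)
  fold_of <- ((seq_len(n) - 1L) %/% fold_size) + 1L
  unname(split(seq_len(n), fold_of))
}

#' Sequential leave-eleven-out cross-validation of segmentation
#'
#' Partitions the cases sequentially into disjoint test folds of
#' `fold_size` (default 11), the final fold absorbing the remainder (63
#' cases give fold sizes 11, 11, 11, 11, 11, 8). Every case appears in
#' exactly one test fold. Per fold, each test case is segmented with the
#' supplied configuration and every recovered vertebra is scored against
#' its ground-truth mask; metrics are aggregated per lumbar level and
#' overall.
#'
#' @param cases list of `"phantom_case"` objects (or any objects with
#'   `image`, `truth_masks`, `labels`).
#' @param config a [seg_config()].
#' @param fold_size test-fold size (default 11).
#' @param preprocess function applied to each image before segmentation
#'   (default: 3x3 median smoothing).
#' @return list with `folds` (per-fold index sets), `per_vb` (data.frame:
#'   case, level, fold, accuracy, sensitivity, dsc, jaccard), `per_level`
#'   (mean metrics per level) and `summary` (overall means).
#' @export
leave_eleven_out_cv <- function(cases, config = seg_config(), fold_size = 11L,
                                preprocess = function(img) spatial_filter(img, "median", 3L)) {
  n <- length(cases)
  folds <- sequential_folds(n, fold_size)
  rows <- list()
  for (f in seq_along(folds)) {
    for (ci in folds[[f]]) {
      case <- cases[[ci]]
      img <- preprocess(case$image)
      regions <- tryCatch(suppressWarnings(segment_pipeline(img, config)),
                          error = function(e) list())
      found <- stats::setNames(lapply(regions, `[[`, "mask"),
                               vapply(regions, `[[`, "", "level"))
      for (lv in names(case$truth_masks)) {
        pred <- found[[lv]]
        if (is.null(pred)) pred <- matrix(0L, nrow(case$image), ncol(case$image))
        met <- seg_metrics(confusion(pred, case$truth_masks[[lv]]))
        rows[[length(rows) + 1L]] <- data.frame(
          case = ci, level = lv, fold = f,
          accuracy = as.numeric(met$accuracy),
          sensitivity = as.numeric(met$sensitivity),
          dsc = as.numeric(met$dsc), jaccard = as.numeric(met$jaccard))
      }
    }
  }
  per_vb <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "dsc", "jaccard")
  per_level <- stats::aggregate(per_vb[, metric_cols],
                                by = list(level = per_vb$level), mean)
  list(folds = folds, per_vb = per_vb, per_level = per_level,
       summary = colMeans(per_vb[, metric_cols]))
}

#' Paired t-test on matched per-split accuracies
#'
#' Two-sided paired t-test, `t = mean(d) / (sd(d) / sqrt(n))` with the
#' sample (n-1) standard deviation and a t reference distribution on n-1
#' degrees of freedom.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return list with `t`, `p`, `df`, `n`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) stop("degenerate paired test: zero-variance differences", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = length(a))
}

# Exact null distribution of the positive signed-rank sum W+ over all 2^n
# sign assignments, by the generating-function recursion
# Prod_i (1 + x^{r_i}). Ranks are doubled so tied |d| (average ranks, .5)
# stay integral. Returns counts over 2*W+ = 0 .. sum(2*r).
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test with the null distribution of the signed-rank sum
#' enumerated exactly over all 2^n sign assignments (tied absolute
#' differences receive average ranks; zero differences are dropped with a
#' warning and n reduced). The reported statistic W is the smaller of the
#' positive- and negative-rank sums; the two-sided p-value is
#' `min(1, 2 * min(P(W+ <= w+), P(W+ >= w+)))`. With n = 6 one-signed
#' differences this gives W = 0, p = 2/2^6 = 0.03125.
#'
#' @param a,b numeric vectors of equal length, n pairs (n <= 25).
#' @return list with `W`, `W_plus`, `W_minus`, `p`, `n` (pairs used).
#' @export
wilcoxon_signed_rank_exact <- function(a, b) {
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  d <- a - b
  if (any(d == 0)) {
    warning(sprintf("dropping %d zero difference(s)", sum(d == 0)))
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  if (n > 25) stop("exact enumeration limited to n <= 25 pairs", call. = FALSE)
  r <- rank(abs(d))                      # average ranks for ties
  ranks2 <- as.integer(round(2 * r))
  w_plus2 <- sum(ranks2[d > 0])
  counts <- signed_rank_counts(ranks2)
  total <- 2^n
  p_le <- sum(counts[seq_len(w_plus2 + 1)]) / total
  p_ge <- sum(counts[(w_plus2 + 1):length(counts)]) / total
  w_plus <- w_plus2 / 2
  w_minus <- sum(r) - w_plus
  list(W = min(w_plus, w_minus), W_plus = w_plus, W_minus = w_minus,
       p = min(1, 2 * min(p_le, p_ge)), n = n)
}

#' Compare KNN arms against the SVM arm
#'
#' Pairs each KNN configuration's per-split accuracies with the SVM
#' accuracies on the same splits and reports the paired t and exact
#' Wilcoxon signed-rank statistics for each comparison.
#'
#' @param knn_accuracies named list: one numeric vector of per-split
#'   accuracies per k (names used in the report).
#' @param svm_accuracies numeric vector of SVM per-split accuracies
#'   (matched ordering).
#' @return data.frame: `comparison`, `t`, `t_p`, `W`, `w_p`, `n`.
#' @export
compare_classifiers <- function(knn_accuracies, svm_accuracies) {
  rows <- lapply(names(knn_accuracies), function(nm) {
    a <- knn_accuracies[[nm]]
    tt <- paired_t_test(a, svm_accuracies)
    wt <- wilcoxon_signed_rank_exact(a, svm_accuracies)
    data.frame(comparison = paste0(nm, " vs svm"),
               t = tt$t, t_p = tt$p, W = wt$W, w_p = wt$p, n = tt$n)
  })
  do.call(rbind, rows)
}
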