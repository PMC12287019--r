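test_that("confusion counts match an exhaustive hand count", {
  a <- matrix(c(1, 1, 0, 0), 2, 2); b <- matrix(c(1, 0, 1, 0), 2, 2)
  cm <- confusion(a, b)
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 1, TN = 1, FP = 1, FN = 1))
  same <- confusion(a, a)
  expect_equal(same$FP + same$FN, 0)
  inv <- confusion(a, 1 - a)
  expect_equal(inv$TP + inv$TN, 0)
  set.seed(13)
  p <- matrix(rbinom(64, 1, 0.5), 8, 8); t_ <- matrix(rbinom(64, 1, 0.5), 8, 8)
  cm2 <- confusion(p, t_)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (p[i, j] == 1 && t_[i, j] == 1) tp <- tp + 1
    if (p[i, j] == 0 && t_[i, j] == 0) tn <- tn + 1
    if (p[i, j] == 1 && t_[i, j] == 0) fp <- fp + 1
    if (p[i, j] == 0 && t_[i, j] == 1) fn <- fn + 1
  }
  expect_equal(unlist(cm2[c("TP", "TN", "FP", "FN")]),
               c(TP = tp, TN = tn, FP = fp, FN = fn))
})

test_that("segmentation metrics follow their defining ratios", {
  cm <- structure(list(TP = 50, TN = 30, FP = 10, FN = 10), class = "confusion")
  sm <- seg_metrics(cm)
  expect_equal(as.numeric(sm$dsc), 100 * 100 / 120)
  expect_equal(as.numeric(sm$jaccard), 100 * 50 / 70)
  expect_equal(as.numeric(sm$accuracy), 80)
  expect_equal(as.numeric(sm$sensitivity), 100 * 50 / 60)
  m <- matrix(rbinom(100, 1, 0.5), 10, 10)
  perfect <- seg_metrics(confusion(m, m))
  expect_equal(as.numeric(unlist(perfect[c("accuracy", "sensitivity", "dsc", "jaccard")])),
               rep(100, 4))
})

test_that("DSC and Jaccard satisfy DSC = 2J/(1+J) on random counts", {
  set.seed(17)
  for (i in 1:500) {
    cm <- structure(as.list(stats::setNames(sample(0:40, 4, TRUE),
                                            c("TP", "TN", "FP", "FN"))),
                    class = "confusion")
    if (cm$TP + cm$FP + cm$FN == 0) next
    sm <- seg_metrics(cm)
    j <- as.numeric(sm$jaccard) / 100
    expect_equal(as.numeric(sm$dsc) / 100, 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("classification metrics and degenerate handling behave", {
  cm <- structure(list(TP = 98, TN = 0, FP = 2, FN = 0), class = "confusion")
  expect_equal(as.numeric(cls_metrics(cm)$precision), 98)
  allc <- structure(list(TP = 40, TN = 60, FP = 0, FN = 0), class = "confusion")
  mets <- cls_metrics(allc)
  expect_equal(as.numeric(unlist(mets[c("accuracy", "precision", "recall", "f1")])),
               rep(100, 4))
  set.seed(19)
  v <- sample(1:50, 4); names(v) <- c("TP", "TN", "FP", "FN")
  got <- cls_metrics(structure(as.list(v), class = "confusion"))
  prec <- 100 * v["TP"] / (v["TP"] + v["FP"])
  rec <- 100 * v["TP"] / (v["TP"] + v["FN"])
  expect_equal(as.numeric(got$precision), unname(prec))
  expect_equal(as.numeric(got$f1), unname(2 * prec * rec / (prec + rec)))
  # empty prediction: all metrics defined, flagged degenerate
  none <- structure(list(TP = 0, TN = 10, FP = 0, FN = 5), class = "confusion")
  dm <- cls_metrics(none)
  expect_equal(as.numeric(dm$precision), 0)
  expect_true(dm$degenerate)
})

test_that("accuracy is invariant under the TP/TN, FP/FN swap", {
  set.seed(23)
  for (i in 1:20) {
    v <- sample(0:30, 4, TRUE)
    a <- structure(list(TP = v[1], TN = v[2], FP = v[3], FN = v[4]), class = "confusion")
    b <- structure(list(TP = v[2], TN = v[1], FP = v[4], FN = v[3]), class = "confusion")
    expect_equal(as.numeric(seg_metrics(a)$accuracy), as.numeric(seg_metrics(b)$accuracy))
  }
})

test_that("sequential folds partition the cases with a short last fold", {
  f63 <- sequential_folds(63, 11)
  expect_equal(unname(lengths(f63)), c(11, 11, 11, 11, 11, 8))
  expect_equal(sort(unname(unlist(f63))), 1:63)
  f22 <- sequential_folds(22, 11)
  expect_equal(unname(lengths(f22)), c(11, 11))
  for (n in c(12, 23, 37, 100)) {
    f <- sequential_folds(n, 11)
    expect_equal(sort(unname(unlist(f))), 1:n)   # disjoint cover
    expect_true(all(lengths(f) <= 11))
  }
  expect_error(sequential_folds(11, 11), "need more than")
})

test_that("leave-eleven-out segmentation evaluation covers every vertebra", {
  spec <- phantom_spec(image_height = 96, image_width = 72, n_vertebrae = 2L,
                       vb_height = 16, vb_width = 26, disc_gap = 8,
                       corner_radius = 3, noise_sd = 3)
  ds <- generate_dataset(spec, n_cases = 12, fracture_prevalence = 0.3, seed = 8)
  cv <- leave_eleven_out_cv(ds$cases, seg_config(expected_n = 2), fold_size = 11)
  expect_equal(unname(lengths(cv$folds)), c(11, 1))
  expect_equal(nrow(cv$per_vb), 12 * 2)
  expect_equal(sort(unique(cv$per_vb$case)), 1:12)
  expect_true(all(cv$per_level$dsc >= 0 & cv$per_level$dsc <= 100))
  expect_gt(cv$summary[["dsc"]], 90)
})

test_that("the paired t-test matches its closed form and is antisymmetric", {
  a <- c(5.1, 6.0, 4.8, 7.2, 6.6); b <- c(4.0, 5.5, 5.0, 6.1, 5.9)
  got <- paired_t_test(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_manual), length(d) - 1), tolerance = 1e-12)
  rev <- paired_t_test(b, a)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)
  # zero-mean symmetric differences give t = 0
  base <- c(10, 20, 30, 40, 50, 60)
  sym <- paired_t_test(base + c(-1, 1, -2, 2, -3, 3), base)
  expect_equal(sym$t, 0)
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "degenerate|constant")
})

test_that("exact Wilcoxon reproduces enumeration, including ties", {
  # six one-signed differences: W = 0, p = 2/64
  a <- c(1, 2, 3, 4, 5, 6); b <- a + c(2, 1, 3, 2, 4, 1)
  w <- wilcoxon_signed_rank_exact(a, b)
  expect_equal(w$W, 0)
  expect_equal(w$p, 0.03125)
  # single pair: both sign assignments equally extreme
  w1 <- wilcoxon_signed_rank_exact(3, 1)
  expect_equal(w1$p, 1)
  # random tie-free differences vs full enumeration and wilcox.test
  set.seed(29)
  for (i in 1:5) {
    x <- round(rnorm(8), 3); y <- round(rnorm(8), 3)
    got <- wilcoxon_signed_rank_exact(x, y)
    expect_equal(got$p, wilcoxon_enum(x - y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$W_plus, unname(ref$statistic))
  }
  # tied absolute differences take average ranks; enumeration still exact
  xt <- c(5, 7, 9, 11, 13, 2, 4); yt <- c(4, 6, 8, 12, 14, 4, 1)
  expect_equal(wilcoxon_signed_rank_exact(xt, yt)$p, wilcoxon_enum(xt - yt),
               tolerance = 1e-12)
  # zeros are dropped with a warning; all-zero input errors
  expect_warning(wz <- wilcoxon_signed_rank_exact(c(1, 2, 3, 4), c(1, 1, 1, 1)),
                 "zero difference")
  expect_equal(wz$n, 3)
  expect_error(suppressWarnings(wilcoxon_signed_rank_exact(1:3, 1:3)), "zero")
})

test_that("the exact signed-rank null distribution is a probability measure", {
  for (n in c(3, 6, 10, 12)) {
    counts <- vbseg:::signed_rank_counts(2L * seq_len(n))
    expect_equal(sum(counts), 2^n)
    # symmetric about n(n+1)/2 (on the doubled scale)
    expect_equal(counts, rev(counts))
  }
})

test_that("classifier comparison reports one row per KNN arm", {
  knn <- list(k3 = c(70, 75, 80, 85, 90, 95), k5 = c(60, 65, 70, 72, 74, 76))
  svm <- c(95, 96, 97, 98, 96, 98)
  cmp <- compare_classifiers(knn, svm)
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$comparison, c("k3 vs svm", "k5 vs svm"))
  expect_true(all(cmp$t < 0))
  expect_true(all(cmp$w_p <= 0.05))
  expect_equal(cmp$n, c(6, 6))
})
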