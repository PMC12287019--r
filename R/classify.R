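## Binary normal-vs-fractured classification: k-nearest neighbours with
## Euclidean distance and majority vote, and a linear soft-margin SVM
## trained by SMO on the dual, plus the split/hyperparameter grid protocol.

#' k-nearest-neighbour prediction
#'
#' Euclidean distances from each query to every training row; the label is
#' the majority class among the k nearest, the posterior the class fraction
#' among those neighbours. Distance ties are broken by lower training-row
#' index; an odd `k` avoids vote ties in the binary problem (a tied vote,
#' possible for even `k`, goes to the smaller label).
#'
#' @param train_x numeric training matrix.
#' @param train_y integer labels (0/1).
#' @param query numeric matrix of query rows (same column count).
#' @param k neighbourhood size, `1 <= k <= nrow(train_x)`.
#' @return list with `labels` (integer vector) and `posterior` (matrix with
#'   columns `p0`, `p1` of neighbour class fractions).
#' @export
knn_predict <- function(train_x, train_y, query, k = 3L) {
  train_x <- as.matrix(train_x); query <- as.matrix(query)
  train_y <- as.integer(train_y)
  if (ncol(train_x) != ncol(query)) stop("feature dimension mismatch", call. = FALSE)
  n <- nrow(train_x)
  if (k < 1 || k > n) stop_field("k", "must lie in 1..nrow(train_x)")
  # squared Euclidean distances, all pairs at once
  d2 <- outer(rowSums(query^2), rowSums(train_x^2), `+`) -
    2 * query %*% t(train_x)
  m <- nrow(query)
  labels <- integer(m)
  post <- matrix(0, m, 2, dimnames = list(NULL, c("p0", "p1")))
  for (i in seq_len(m)) {
    nbr <- order(d2[i, ], seq_len(n))[seq_len(k)]   # stable: index breaks ties
    p1 <- mean(train_y[nbr] == 1L)
    post[i, ] <- c(1 - p1, p1)
    labels[i] <- if (p1 > 0.5) 1L else 0L
  }
  list(labels = labels, posterior = post)
}

#' Train a linear soft-margin SVM
#'
#' Minimizes the primal objective
#' `0.5 * ||w||^2 + C * sum_i max(0, 1 - y_i (w . x_i + b))`
#' by solving the box-constrained dual with sequential minimal optimization
#' (maximal-violating-pair working-set selection), which is deterministic
#' for fixed inputs. The decision rule is `sign(w . x + b)`.
#'
#' @param x numeric training matrix (callers standardize; the grid protocol
#'   z-scores with training-split statistics).
#' @param y labels in \{0, 1\} (mapped internally to -1/+1) — both classes
#'   must be present.
#' @param C regularization weight (> 0): trade-off between margin width and
#'   hinge violations.
#' @param tol KKT violation tolerance of the SMO stopping rule.
#' @param max_iter iteration cap.
#' @return object of class `"svm_model"`: `w`, `b`, `C`, `alpha`,
#'   `support_flags` (rows with `|w . x + b| <= 1 + 1e-3`), `objective`
#'   (primal value at the solution), `iterations`, `converged`.
#' @export
svm_train <- function(x, y, C = 1, tol = 1e-5, max_iter = 100000L) {
  x <- as.matrix(x)
  y01 <- as.integer(y)
  if (length(unique(y01)) < 2) stop("training data contain a single class", call. = FALSE)
  if (C <= 0) stop_field("C", "must be > 0")
  yy <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(x)
  K <- x %*% t(x)
  Q <- (yy %o% yy) * K
  alpha <- numeric(n)
  G <- rep(-1, n)                      # gradient of 0.5 a'Qa - e'a
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    yg <- -yy * G
    up <- (alpha < C - 1e-12 & yy > 0) | (alpha > 1e-12 & yy < 0)
    lo <- (alpha < C - 1e-12 & yy < 0) | (alpha > 1e-12 & yy > 0)
    if (!any(up) || !any(lo)) { converged <- TRUE; break }
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < tol) { converged <- TRUE; break }
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]   # d'Qd for d_i = y_i, d_j = -y_j
    if (quad <= 1e-12) quad <- 1e-12
    t_star <- (yy[j] * G[j] - yy[i] * G[i]) / quad
    # feasible direction d_i = y_i, d_j = -y_j keeps sum(alpha * y) fixed;
    # clip so both alphas stay inside [0, C]
    t_lo <- max(if (yy[i] > 0) -alpha[i] else alpha[i] - C,
                if (yy[j] > 0) alpha[j] - C else -alpha[j])
    t_hi <- min(if (yy[i] > 0) C - alpha[i] else alpha[i],
                if (yy[j] > 0) alpha[j] else C - alpha[j])
    t_step <- min(max(t_star, t_lo), t_hi)
    if (abs(t_step) < 1e-15) { converged <- TRUE; break }
    alpha[i] <- alpha[i] + yy[i] * t_step
    alpha[j] <- alpha[j] - yy[j] * t_step
    G <- G + t_step * (yy[i] * Q[, i] - yy[j] * Q[, j])
    if (it >= max_iter) break
  }
  w <- as.numeric(t(x) %*% (alpha * yy))
  # bias from the optimality interval midpoint (= mean over free support
  # vectors when any exist); note -y_i G_i = y_i - w . x_i for linear K
  yg <- -yy * G
  up <- (alpha < C - 1e-12 & yy > 0) | (alpha > 1e-12 & yy < 0)
  lo <- (alpha < C - 1e-12 & yy < 0) | (alpha > 1e-12 & yy > 0)
  b <- if (any(up) && any(lo)) (max(yg[up]) + min(yg[lo])) / 2 else 0
  f <- as.numeric(x %*% w + b)
  obj <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - yy * f))
  structure(list(w = w, b = b, C = C, alpha = alpha,
                 support_flags = abs(f) <= 1 + 1e-3,
                 objective = obj, iterations = it, converged = converged),
            class = "svm_model")
}

#' Linear SVM prediction
#'
#' `sign(w . x + b)` mapped to 0/1 labels; a point exactly on the boundary
#' is assigned to the positive (fractured) class.
#'
#' @param model `"svm_model"` from [svm_train()].
#' @param x query matrix.
#' @return integer labels; attribute `"decision"` carries `w . x + b`.
#' @export
svm_predict <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  f <- as.numeric(as.matrix(x) %*% model$w + model$b)
  out <- ifelse(f >= 0, 1L, 0L)
  attr(out, "decision") <- f
  out
}

#' Select the SVM regularization weight by cross-validation
#'
#' Plain k-fold cross-validated accuracy over a C grid on (already
#' standardized) training data; ties go to the smaller C (stronger
#' regularization).
#'
#' @param x,y training data.
#' @param C_grid candidate values (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param n_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `C` (the winner) and `cv_accuracy` (per-candidate).
#' @export
svm_tune_C <- function(x, y, C_grid = c(0.01, 0.1, 1, 10, 100),
                       n_folds = 5L, seed = 1L) {
  x <- as.matrix(x); y <- as.integer(y)
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  acc <- vapply(C_grid, function(C) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      mod <- svm_train(x[tr, , drop = FALSE], y[tr], C = C)
      correct <- correct + sum(svm_predict(mod, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / n
  }, numeric(1))
  list(C = C_grid[which.max(acc)], cv_accuracy = stats::setNames(acc, C_grid))
}

# Stratified train/test split: returns logical vector, TRUE = training row.
stratified_split <- function(y, train_fraction, seed) {
  with_seed(seed, {
    tr <- logical(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
}

#' Split/hyperparameter grid protocol for KNN and linear SVM
#'
#' For every train fraction, seed replicate and classifier arm: draw a
#' stratified split, z-score features with training-split statistics,
#' SMOTE-balance the training rows only, fit, and score accuracy /
#' precision / recall / F-measure on the untouched test rows.
#'
#' @param dataset a [labeled_dataset()].
#' @param k_values KNN neighbourhood sizes (default `c(3, 5, 7, 9, 11)`).
#' @param train_fractions training-set proportions
#'   (default `c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8)`).
#' @param C SVM regularization weight used for every split (fixed by
#'   default; see [svm_tune_C()] for data-driven selection).
#' @param n_seeds number of seeded replicates per cell.
#' @param seed master seed.
#' @param smote_ratio minority/majority target ratio for training-side
#'   SMOTE (`NULL` disables balancing).
#' @return data.frame with one row per (classifier, parameter, split, seed):
#'   columns `classifier`, `param`, `train_fraction`, `seed_rep`,
#'   `accuracy`, `precision`, `recall`, `f1` (percentages).
#' @seealso [results_table()] for the per-split table with its Average row.
#' @export
grid_search <- function(dataset, k_values = c(3L, 5L, 7L, 9L, 11L),
                        train_fractions = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
                        C = 1, n_seeds = 1L, seed = 1L, smote_ratio = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  rows <- list()
  for (rep_i in seq_len(n_seeds)) {
    for (fr in train_fractions) {
      split_seed <- derive_seed(seed, sprintf("split_%0.2f_%d", fr, rep_i))
      tr <- stratified_split(dataset$y, fr, split_seed)
      if (length(unique(dataset$y[tr])) < 2 || length(unique(dataset$y[!tr])) < 2) {
        stop(sprintf("split %.2f leaves a class empty", fr), call. = FALSE)
      }
      mu <- colMeans(dataset$x[tr, , drop = FALSE])
      sd_ <- apply(dataset$x[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0 | is.na(sd_)] <- 1
      xs <- sweep(sweep(dataset$x, 2, mu), 2, sd_, `/`)
      train <- labeled_dataset(xs[tr, , drop = FALSE], dataset$y[tr],
                               dataset$case_id[tr])
      if (!is.null(smote_ratio)) {
        k_sm <- min(5L, sum(train$y == 1L) - 1L, sum(train$y == 0L) - 1L)
        if (k_sm >= 1L) {
          train <- smote(train, k_neighbors = k_sm, target_ratio = smote_ratio,
                         seed = derive_seed(seed, sprintf("smote_%0.2f_%d", fr, rep_i)))
        }
      }
      x_te <- xs[!tr, , drop = FALSE]; y_te <- dataset$y[!tr]
      score <- function(pred) {
        cm <- confusion(pred, y_te, positive = 1L)
        met <- cls_metrics(cm)
        c(met$accuracy, met$precision, met$recall, met$f1)
      }
      for (k in k_values) {
        if (k > nrow(train$x)) next
        s <- score(knn_predict(train$x, train$y, x_te, k = k)$labels)
        rows[[length(rows) + 1L]] <- data.frame(
          classifier = "knn", param = k, train_fraction = fr, seed_rep = rep_i,
          accuracy = s[1], precision = s[2], recall = s[3], f1 = s[4])
      }
      mod <- svm_train(train$x, train$y, C = C)
      s <- score(svm_predict(mod, x_te))
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = "svm", param = C, train_fraction = fr, seed_rep = rep_i,
        accuracy = s[1], precision = s[2], recall = s[3], f1 = s[4])
    }
  }
  do.call(rbind, rows)
}

#' Per-split results table with Average row
#'
#' Reshapes [grid_search()] output for one classifier arm into the standard
#' per-split metric table (one row per train:test split, metrics averaged
#' over seed replicates) and appends an `Average` row holding the arithmetic
#' column means over splits.
#'
#' @param results data.frame from [grid_search()].
#' @param classifier `"knn"` or `"svm"`.
#' @param param the k (KNN) or C (SVM) to select.
#' @return data.frame with columns `split`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
results_table <- function(results, classifier, param) {
  sub <- results[results$classifier == classifier & results$param == param, ]
  if (nrow(sub) == 0) stop("no matching rows", call. = FALSE)
  ag <- stats::aggregate(sub[, c("accuracy", "precision", "recall", "f1")],
                         by = list(train_fraction = sub$train_fraction), mean)
  ag <- ag[order(ag$train_fraction), ]
  out <- data.frame(
    split = sprintf("%d-%d", round(100 * ag$train_fraction),
                    round(100 * (1 - ag$train_fraction))),
    ag[, c("accuracy", "precision", "recall", "f1")])
  rbind(out, data.frame(split = "Average",
                        accuracy = mean(out$accuracy),
                        precision = mean(out$precision),
                        recall = mean(out$recall),
                        f1 = mean(out$f1)))
}
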