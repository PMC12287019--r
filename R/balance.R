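## Class balancing: SMOTE in feature space and rotation augmentation in
## image space. Balancing is meant to be applied inside a fixed training
## split only, never to test rows (the grid protocol enforces this).

#' Labelled feature dataset
#'
#' Thin container holding a numeric feature matrix with parallel binary
#' labels (0 = normal, 1 = fractured), case identifiers and a per-row
#' provenance flag (`"original"`, `"synthetic"`, `"augmented"`).
#'
#' @param x numeric matrix (rows = samples).
#' @param y integer labels in \{0, 1\}.
#' @param case_id character identifiers (defaults to row numbers).
#' @param provenance character flags (defaults to `"original"`).
#' @return list of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(x, y, case_id = NULL, provenance = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  case_id <- case_id %||% sprintf("row%04d", seq_len(nrow(x)))
  provenance <- provenance %||% rep("original", nrow(x))
  if (length(case_id) != nrow(x) || length(provenance) != nrow(x)) {
    stop("case_id/provenance length mismatch", call. = FALSE)
  }
  structure(list(x = x, y = y, case_id = as.character(case_id),
                 provenance = as.character(provenance)),
            class = "labeled_dataset")
}

#' SMOTE oversampling of the minority class
#'
#' For each synthetic sample a minority row `x` is drawn, one of its
#' `k_neighbors` nearest minority neighbours `x_n` (Euclidean) is picked,
#' and the new row is `x + u * (x_n - x)` with `u ~ Uniform(0, 1)`, i.e. a
#' random point on the segment joining the two. Original rows are never
#' altered, removed or relabelled; synthetic rows are flagged
#' `"synthetic"`.
#'
#' @param dataset a [labeled_dataset()].
#' @param k_neighbors neighbourhood size (default 5).
#' @param target_ratio desired minority/majority count ratio in
#'   `(current ratio, 1]`; enough synthetic rows are added to reach at least
#'   this ratio.
#' @param seed integer seed (deterministic output).
#' @param u_override optional fixed interpolation weight in `[0, 1]`
#'   (testing hook; `u_override = 0` duplicates parents exactly).
#' @return a new `labeled_dataset` with the synthetic rows appended.
#' @export
smote <- function(dataset, k_neighbors = 5L, target_ratio = 1, seed = 1L,
                  u_override = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  counts <- table(factor(dataset$y, levels = c(0L, 1L)))
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  n_min <- min(counts); n_maj <- max(counts)
  if (target_ratio <= n_min / n_maj) return(dataset)
  if (target_ratio > 1) stop_field("target_ratio", "must be <= 1")
  if (n_min < k_neighbors + 1) {
    stop(sprintf("minority class has %d samples; SMOTE with k = %d needs at least %d",
                 n_min, k_neighbors, k_neighbors + 1), call. = FALSE)
  }
  n_new <- ceiling(target_ratio * n_maj) - n_min
  min_idx <- which(dataset$y == minority)
  xm <- dataset$x[min_idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(xm))^2
  diag(d2) <- Inf
  ord <- apply(d2, 1, function(r) order(r)[seq_len(k_neighbors)])
  nn <- if (k_neighbors == 1L) matrix(ord, ncol = 1L) else t(ord)
  syn <- with_seed(seed, {
    parents <- sample(seq_len(n_min), n_new, replace = TRUE)
    nb_pick <- sample(seq_len(k_neighbors), n_new, replace = TRUE)
    u <- if (is.null(u_override)) stats::runif(n_new) else rep(u_override, n_new)
    xp <- xm[parents, , drop = FALSE]
    xn <- xm[nn[cbind(parents, nb_pick)], , drop = FALSE]
    xp + u * (xn - xp)
  })
  labeled_dataset(
    rbind(dataset$x, syn),
    c(dataset$y, rep(minority, n_new)),
    c(dataset$case_id, sprintf("smote%04d", seq_len(n_new))),
    c(dataset$provenance, rep("synthetic", n_new)))
}

# Rotate a matrix by `angle` degrees about the image centre using inverse
# mapping; interp = "bilinear" (images) or "nearest" (masks).
rotate_matrix <- function(m, angle, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  out_r <- rep(seq_len(h), times = w); out_c <- rep(seq_len(w), each = h)
  dy <- out_r - cy; dx <- out_c - cx
  # inverse rotation of the output grid into source coordinates
  src_x <- cos(th) * dx + sin(th) * dy + cx
  src_y <- -sin(th) * dx + cos(th) * dy + cy
  if (interp == "nearest") {
    sr <- round(src_y); sc <- round(src_x)
    ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
    v <- rep(fill, h * w)
    v[ok] <- m[cbind(sr[ok], sc[ok])]
  } else {
    r0 <- floor(src_y); c0 <- floor(src_x)
    fr <- src_y - r0; fc <- src_x - c0
    v <- rep(as.numeric(fill), h * w)
    gv <- function(r, c) {
      ok <- r >= 1 & r <= h & c >= 1 & c <= w
      out <- rep(as.numeric(fill), length(r))
      out[ok] <- m[cbind(r[ok], c[ok])]
      out
    }
    v <- (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
      fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
  }
  matrix(v, h, w)
}

#' Rotation augmentation
#'
#' Rotates an image and its ground-truth masks by the same small angles
#' about the image centre (bilinear interpolation for the image, nearest
#' neighbour for masks), carrying labels unchanged. Angles must lie within
#' the +/- 15 degree range typical of patient positioning variation.
#'
#' @param image integer gray matrix.
#' @param masks list of 0/1 matrices (may be empty).
#' @param angles numeric vector of rotation angles in degrees, each in
#'   `[-15, 15]`; if `NULL`, `n_draws` angles are drawn uniformly.
#' @param n_draws number of random angles when `angles` is `NULL`.
#' @param seed seed for the random draw.
#' @return list with one element per angle: `list(angle, image, masks)`.
#' @export
rotate_augment <- function(image, masks = list(), angles = NULL,
                           n_draws = 1L, seed = 1L) {
  if (is.null(angles)) {
    angles <- with_seed(seed, stats::runif(n_draws, -15, 15))
  }
  if (any(angles < -15 | angles > 15)) {
    stop_field("angles", "must lie within [-15, 15] degrees")
  }
  lapply(angles, function(a) {
    img_r <- as_gray(pmin(pmax(round_half_up(
      rotate_matrix(as_gray(image), a, "bilinear")), 0), 255))
    msk_r <- lapply(masks, function(m) as_mask(rotate_matrix(as_mask(m), a, "nearest")))
    list(angle = a, image = img_r, masks = msk_r)
  })
}
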