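## Vertebral-body segmentation: thresholding, morphology, component
## filtering, convex-hull regularization and top-to-bottom labelling.

#' Otsu threshold of a gray image
#'
#' Exhaustive search for the threshold maximizing the between-class variance
#' of the gray-level histogram.
#'
#' @param img integer gray matrix.
#' @param L number of gray levels.
#' @return threshold t (foreground = pixels with value > t).
#' @export
otsu_threshold <- function(img, L = 256L) {
  img <- as_gray(img, L)
  h <- tabulate(as.vector(img) + 1L, nbins = L)
  if (sum(h > 0) < 2) stop("degenerate histogram: image has a single gray level", call. = FALSE)
  p <- h / sum(h)
  levels <- 0:(L - 1)
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[L]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  levels[which.max(sigma_b)]
}

#' Binarize a gray image
#'
#' @param img integer gray matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param t threshold for `method = "fixed"`; foreground = pixels `> t`.
#' @return 0/1 integer mask of the same shape.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), t = NULL) {
  method <- match.arg(method)
  img <- as_gray(img)
  thr <- if (method == "otsu") otsu_threshold(img) else {
    if (is.null(t)) stop_field("t", "fixed threshold required")
    t
  }
  m <- (img > thr) * 1L
  attr(m, "threshold") <- thr
  as_mask(m)
}

#' Filter connected components by area and centroid-x alignment
#'
#' Two-stage cleanup after morphology: (i) components smaller than
#' `min_area_fraction` times the largest component are discarded as islands;
#' (ii) of the remainder, only components whose centroid x-coordinate lies
#' within `centroid_band_fraction * image_width` of the median centroid-x
#' are kept, exploiting the vertical alignment of the vertebral column.
#'
#' @param mask 0/1 matrix with at least one component.
#' @param min_area_fraction relative island-area threshold in (0, 1].
#' @param centroid_band_fraction half-width of the centroid-x band as a
#'   fraction of image width, in (0, 1].
#' @return filtered 0/1 mask.
#' @export
filter_components <- function(mask, min_area_fraction = 0.05,
                              centroid_band_fraction = 0.15) {
  m <- as_mask(mask)
  if (min_area_fraction <= 0 || min_area_fraction > 1) {
    stop_field("min_area_fraction", "must lie in (0, 1]")
  }
  if (centroid_band_fraction <= 0 || centroid_band_fraction > 1) {
    stop_field("centroid_band_fraction", "must lie in (0, 1]")
  }
  lab <- label_components(m, 8L)
  if (max(lab) == 0) stop("no components in mask", call. = FALSE)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_fraction * max(areas))
  cx <- vapply(keep, function(l) mean(((which(lab == l) - 1L) %/% nrow(m))), numeric(1))
  med <- stats::median(cx)
  keep <- keep[abs(cx - med) <= centroid_band_fraction * ncol(m)]
  out <- matrix(0L, nrow(m), ncol(m))
  out[lab %in% keep] <- 1L
  as_mask(out)
}

#' Replace each component by its filled convex hull
#'
#' Every 8-connected component is independently replaced by the set of
#' pixels lying inside the convex hull of its pixel centres, regularizing
#' irregular (e.g. collapsed) boundaries while preserving overall structure.
#' The output is a superset of the input.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 mask with convexified components.
#' @export
convex_hull_regions <- function(mask) {
  m <- as_mask(mask)
  lab <- label_components(m, 8L)
  out <- matrix(0L, nrow(m), ncol(m))
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    xs <- (idx - 1L) %/% nrow(m); ys <- (idx - 1L) %% nrow(m)
    if (length(idx) <= 2) { out[idx] <- 1L; next }
    hull_idx <- grDevices::chull(xs, ys)
    hx <- xs[hull_idx]; hy <- ys[hull_idx]
    # candidate pixels: bounding box of the hull
    cx <- min(xs):max(xs); cy <- min(ys):max(ys)
    gx <- rep(cx, each = length(cy)); gy <- rep(cy, length(cx))
    inside <- rep(TRUE, length(gx))
    nh <- length(hx)
    # orientation sign of the hull polygon, so the half-plane test below
    # works for either traversal direction
    hx2 <- c(hx[-1], hx[1]); hy2 <- c(hy[-1], hy[1])
    s <- sign(sum(hx * hy2 - hx2 * hy))
    if (s == 0) s <- 1
    for (i in seq_len(nh)) {
      j <- if (i == nh) 1L else i + 1L
      ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
      cr <- ex * (gy - hy[i]) - ey * (gx - hx[i])
      inside <- inside & (s * cr >= -1e-9)
    }
    sel <- cbind(gy[inside] + 1L, gx[inside] + 1L)
    out[sel] <- 1L
  }
  out <- out | m
  as_mask(out * 1L)
}

#' Label vertebra regions top to bottom
#'
#' Sorts the components of a segmented mask by centroid vertical coordinate
#' and labels them L1 (topmost) downward. Each region carries its mask,
#' traced contour, centroid and area.
#'
#' @param mask 0/1 matrix with at least one component.
#' @param expected_n number of vertebrae expected (default 5). If the mask
#'   holds a different number of components, `min(expected_n, found)` regions
#'   are returned and a warning is raised.
#' @return list of `"vb_region"` objects (fields `level`, `mask`, `contour`,
#'   `centroid`, `area`); attribute `"n_found"` carries the component count.
#' @export
label_vertebrae <- function(mask, expected_n = 5L) {
  m <- as_mask(mask)
  lab <- label_components(m, 8L)
  n_found <- max(lab)
  if (n_found == 0) stop("no components in mask", call. = FALSE)
  if (n_found != expected_n) {
    warning(sprintf("expected %d vertebrae, found %d components", expected_n, n_found))
  }
  cy <- vapply(seq_len(n_found), function(l) mean(((which(lab == l) - 1L) %% nrow(m))), numeric(1))
  ord <- order(cy)[seq_len(min(expected_n, n_found))]
  regions <- lapply(seq_along(ord), function(i) {
    l <- ord[i]
    rm <- matrix(0L, nrow(m), ncol(m))
    rm[lab == l] <- 1L
    structure(list(level = paste0("L", i),
                   mask = rm,
                   contour = trace_contour(rm),
                   centroid = region_centroid(rm),
                   area = sum(rm)),
              class = "vb_region")
  })
  attr(regions, "n_found") <- n_found
  regions
}

#' Default segmentation configuration
#'
#' @param threshold `"otsu"` or `"fixed"`; `threshold_t` used when fixed.
#' @param se_shape,se_radius structuring element of the closing step.
#' @param min_area_fraction,centroid_band_fraction see [filter_components()].
#' @param apply_hull convexify components before labelling.
#' @param expected_n expected vertebra count.
#' @return list of class `"seg_config"`.
#' @export
seg_config <- function(threshold = "otsu", threshold_t = 128L,
                       se_shape = "disk", se_radius = 2L,
                       min_area_fraction = 0.05,
                       centroid_band_fraction = 0.15,
                       apply_hull = TRUE, expected_n = 5L) {
  structure(list(threshold = threshold, threshold_t = threshold_t,
                 se_shape = se_shape, se_radius = se_radius,
                 min_area_fraction = min_area_fraction,
                 centroid_band_fraction = centroid_band_fraction,
                 apply_hull = apply_hull, expected_n = as.integer(expected_n)),
            class = "seg_config")
}

#' Full segmentation pipeline
#'
#' binarize -> morphological closing -> hole filling -> border clearing ->
#' island/centroid filtering -> per-component convex hull -> top-to-bottom
#' labelling. A per-stage component-count log is attached as attribute
#' `"stage_log"`.
#'
#' @param img preprocessed gray image.
#' @param config a [seg_config()].
#' @return list of `"vb_region"` (see [label_vertebrae()]).
#' @export
segment_pipeline <- function(img, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  n_comp <- function(m) max(label_components(m, 8L))
  m <- binarize(img, method = config$threshold, t = config$threshold_t)
  log <- c(binarize = n_comp(m))
  se <- struct_element(config$se_shape, config$se_radius)
  m <- morph_close(m, se);            log <- c(log, closing = n_comp(m))
  m <- fill_holes(m);                 log <- c(log, fill_holes = n_comp(m))
  m <- clear_border(m);               log <- c(log, clear_border = n_comp(m))
  m <- filter_components(m, config$min_area_fraction, config$centroid_band_fraction)
  log <- c(log, filter = n_comp(m))
  if (config$apply_hull) {
    m <- convex_hull_regions(m);      log <- c(log, hull = n_comp(m))
  }
  regions <- label_vertebrae(m, config$expected_n)
  attr(regions, "stage_log") <- log
  regions
}
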