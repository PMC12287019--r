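## Shape features of a segmented vertebral body.
##
## All pixel coordinates are 0-based, (x = column, y = row), y down.
## Eccentricity here follows the pixel-covariance convention: the ratio
## lambda2 / lambda1 of the eigenvalues of the 2 x 2 coordinate covariance
## matrix, so a rotationally symmetric shape scores 1 and elongated shapes
## tend to 0.

fg_coords <- function(mask) {
  m <- as_mask(mask)
  idx <- which(m == 1L)
  cbind(x = ((idx - 1L) %/% nrow(m)), y = ((idx - 1L) %% nrow(m)))
}

#' Region centroid (centre of gravity)
#'
#' Arithmetic mean of the foreground pixel coordinates.
#'
#' @param mask 0/1 matrix.
#' @return named vector `c(gx, gy)` in 0-based pixel coordinates.
#' @export
region_centroid <- function(mask) {
  xy <- fg_coords(mask)
  if (nrow(xy) == 0) stop("empty region", call. = FALSE)
  c(gx = mean(xy[, 1]), gy = mean(xy[, 2]))
}

#' Principal axes, eigenvalues and eccentricity
#'
#' Computes the population covariance matrix of the foreground pixel
#' coordinates, its eigenvalues in closed form, the eccentricity
#' `E = lambda2 / lambda1`, and the axis of least inertia (orientation of
#' the leading eigenvector, reported in `[0, pi)`).
#'
#' @param mask 0/1 matrix with at least 2 foreground pixels.
#' @return list with `lambda1`, `lambda2` (`lambda1 >= lambda2`, pixel^2),
#'   `eccentricity` in `(0, 1]` and `angle` (radians).
#' @export
principal_axes <- function(mask) {
  xy <- fg_coords(mask)
  n <- nrow(xy)
  if (n < 2) stop("degenerate shape: need at least 2 pixels", call. = FALSE)
  gx <- mean(xy[, 1]); gy <- mean(xy[, 2])
  dx <- xy[, 1] - gx; dy <- xy[, 2] - gy
  cxx <- mean(dx * dx); cyy <- mean(dy * dy); cxy <- mean(dx * dy)
  tr <- cxx + cyy
  disc <- sqrt(max(0, tr^2 - 4 * (cxx * cyy - cxy^2)))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (l1 <= 0) stop("degenerate shape: zero leading eigenvalue", call. = FALSE)
  # leading eigenvector
  ang <- if (abs(cxy) > 1e-12) {
    atan2(l1 - cxx, cxy) %% pi
  } else if (cxx >= cyy) 0 else pi / 2
  list(lambda1 = l1, lambda2 = max(0, l2),
       eccentricity = max(0, l2) / l1, angle = ang)
}

#' Average bending energy of a closed contour
#'
#' The contour is resampled to `n_samples` equal arc-length points, its
#' coordinate functions are smoothed by truncating their Fourier series at
#' `n_harmonics` harmonics (Parseval-style evaluation), curvature is
#' evaluated analytically from the Fourier derivatives, and the mean squared
#' curvature is returned. A circle of radius r has bending energy 1 / r^2,
#' the minimum over closed curves of its length.
#'
#' @param contour n x 2 closed polygon (at least 8 vertices).
#' @param n_samples number of equal arc-length samples (default 128).
#' @param n_harmonics harmonics kept in the Fourier smoothing (default 16).
#' @return mean squared curvature (1 / pixel^2).
#' @export
bending_energy <- function(contour, n_samples = 128L, n_harmonics = 16L) {
  p <- as_contour(contour)
  if (nrow(p) < 8) stop("contour must have at least 8 points", call. = FALSE)
  r <- resample_contour(p, n_samples)
  if (!is_simple_polygon(r)) stop("contour is self-intersecting", call. = FALSE)
  n <- n_samples
  z <- stats::fft(complex(real = r[, 1], imaginary = r[, 2]))
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))    # FFT bin frequencies
  keep <- abs(freq) <= n_harmonics
  z[!keep] <- 0
  om <- 2i * pi * freq
  d1 <- stats::fft(z * om, inverse = TRUE) / n       # dz/dt, t in [0,1)
  d2 <- stats::fft(z * om^2, inverse = TRUE) / n
  xp <- Re(d1); yp <- Im(d1); xpp <- Re(d2); ypp <- Im(d2)
  speed2 <- xp^2 + yp^2
  if (any(speed2 < 1e-12)) stop("degenerate contour parameterization", call. = FALSE)
  k <- (xp * ypp - yp * xpp) / speed2^1.5
  mean(k^2)
}

#' Rectangularity
#'
#' Ratio of the region's pixel area to the area of the minimum-area bounding
#' rectangle of its contour (rotating calipers over the convex hull). 1 for
#' a rectangle, pi/4 for a disk, 1/2 for a triangle.
#'
#' @param mask 0/1 matrix (single region).
#' @param contour optional precomputed contour of the region.
#' @return value in `(0, 1]` (up to rasterization error).
#' @export
rectangularity <- function(mask, contour = NULL) {
  m <- as_mask(mask)
  a_s <- sum(m)
  if (a_s == 0) stop("empty region", call. = FALSE)
  if (is.null(contour)) contour <- trace_contour(m)
  a_r <- min_area_rect(contour)$area
  if (a_r <= 0) stop("degenerate bounding rectangle", call. = FALSE)
  a_s / a_r
}

#' Convexity
#'
#' Perimeter of the contour's convex hull divided by the perimeter of the
#' contour itself; 1 for convex shapes, < 1 otherwise (the hull is the
#' shortest closed curve enclosing the points).
#'
#' @param contour n x 2 closed polygon.
#' @return value in `(0, 1]`.
#' @export
convexity <- function(contour) {
  p <- as_contour(contour)
  polygon_perimeter(convex_hull_polygon(p)) / polygon_perimeter(p)
}

#' Euler number
#'
#' Number of 8-connected foreground components minus the number of
#' 4-connected holes.
#'
#' @param mask 0/1 matrix.
#' @return integer.
#' @export
euler_number <- function(mask) {
  m <- as_mask(mask)
  s <- max(label_components(m, 8L))
  bg <- 1L - m
  lab <- label_components(bg, 4L)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  n_holes <- length(setdiff(unique(lab[lab > 0]), border_labs))
  as.integer(s - n_holes)
}

#' Projection profiles
#'
#' Column and row pixel counts of the region indicator over its bounding
#' box: `Pro_x(i) = sum_j f(i, j)` and `Pro_y(j) = sum_i f(i, j)`.
#'
#' @param mask 0/1 matrix.
#' @return list with integer vectors `x` (one entry per bounding-box column)
#'   and `y` (one per row); each sums to the region area.
#' @export
profiles <- function(mask) {
  m <- as_mask(mask)
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  if (length(rows) == 0) stop("empty region", call. = FALSE)
  box <- m[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  list(x = as.integer(colSums(box)), y = as.integer(rowSums(box)))
}

profile_summary <- function(v) {
  m <- mean(v)
  c(len = length(v), max = max(v), mean = m,
    cv = if (m > 0) stats::sd(v) / m else 0)
}

intensity_stats <- function(img, mask) {
  v <- as.numeric(img[as_mask(mask) == 1L])
  if (length(v) == 0) stop("empty region", call. = FALSE)
  mu <- mean(v); s <- stats::sd(v)
  if (length(v) < 2 || is.na(s)) s <- 0
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  c(mean = mu, sd = s, skewness = skew, kurtosis = kurt)
}

#' Extract the full shape-feature set of a vertebra region
#'
#' Assembles centroid, principal-axis eigenvalues and eccentricity, axis of
#' least inertia, bending energy, rectangularity, convexity, Euler number,
#' projection profiles and in-mask intensity moments into one object.
#'
#' @param img gray image the region was segmented from (intensity block).
#' @param region a `"vb_region"` from [label_vertebrae()], or a bare 0/1 mask.
#' @param config list of feature settings; recognised entries:
#'   `n_samples`, `n_harmonics` (bending energy discretization).
#' @return object of class `"vb_features"`; see [feature_vector()] for the
#'   fixed-length numeric encoding used by the classifiers.
#' @export
extract_features <- function(img, region, config = list()) {
  mask <- if (inherits(region, "vb_region")) region$mask else as_mask(region)
  contour <- if (inherits(region, "vb_region")) region$contour else trace_contour(mask)
  ns <- config$n_samples %||% 128L
  nh <- config$n_harmonics %||% 16L
  pa <- principal_axes(mask)
  pr <- profiles(mask)
  structure(list(
    level = if (inherits(region, "vb_region")) region$level else NA_character_,
    centroid = region_centroid(mask),
    area = sum(as_mask(mask)),
    lambda1 = pa$lambda1, lambda2 = pa$lambda2,
    eccentricity = pa$eccentricity,
    inertia_axis_angle = pa$angle,
    bending_energy = bending_energy(contour, ns, nh),
    rectangularity = rectangularity(mask, contour),
    convexity = convexity(contour),
    euler_number = euler_number(mask),
    profile_x = pr$x, profile_y = pr$y,
    intensity = intensity_stats(img, mask)
  ), class = "vb_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixed-order numeric feature vector
#'
#' Encodes a `"vb_features"` object as a fixed-length named numeric vector
#' for classification. Variable-length profiles enter as four summaries per
#' axis (length, max, mean, coefficient of variation). Blocks can be
#' selected; the column order within each block is fixed and documented by
#' the names of the returned vector.
#'
#' @param f object from [extract_features()].
#' @param blocks character subset of `c("shape", "profile", "intensity")`.
#' @return named numeric vector.
#' @export
feature_vector <- function(f, blocks = c("shape", "profile", "intensity")) {
  stopifnot(inherits(f, "vb_features"))
  out <- numeric(0)
  if ("shape" %in% blocks) {
    out <- c(out,
             area = f$area,
             eccentricity = f$eccentricity,
             rectangularity = f$rectangularity,
             convexity = f$convexity,
             euler = as.numeric(f$euler_number),
             bending_energy = f$bending_energy)
  }
  if ("profile" %in% blocks) {
    px <- profile_summary(f$profile_x); py <- profile_summary(f$profile_y)
    names(px) <- paste0("px_", names(px)); names(py) <- paste0("py_", names(py))
    out <- c(out, px, py)
  }
  if ("intensity" %in% blocks) {
    v <- f$intensity; names(v) <- paste0("int_", names(v))
    out <- c(out, v)
  }
  out
}
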