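## Contours and polygon geometry.
##
## A contour is an ordered closed polygon stored as an n x 2 matrix with
## columns (x, y), 0-based pixel coordinates, y increasing downward, first
## vertex NOT repeated at the end. Contours extracted from masks are the
## sub-pixel iso-boundary at level 0.5 (marching squares), oriented clockwise
## on screen and started at the topmost-then-leftmost vertex.

as_contour <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) stop("contour must be an n x 2 matrix, n >= 3", call. = FALSE)
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  colnames(p) <- c("x", "y")
  p
}

polygon_signed_area <- function(p) {
  p <- as_contour(p)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon perimeter (closed arc length)
#' @param p n x 2 vertex matrix of a closed polygon.
#' @export
polygon_perimeter <- function(p) {
  p <- as_contour(p)
  d <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p
  sum(sqrt(rowSums(d^2)))
}

#' Polygon area (absolute shoelace area)
#' @inheritParams polygon_perimeter
#' @export
polygon_area <- function(p) abs(polygon_signed_area(p))

#' Convex hull of a polygon or point set
#' @inheritParams polygon_perimeter
#' @return vertex matrix of the hull, same orientation conventions.
#' @export
convex_hull_polygon <- function(p) {
  p <- as.matrix(p)
  idx <- grDevices::chull(p[, 1], p[, 2])   # clockwise on screen (y down)
  out <- p[idx, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Minimum-area bounding rectangle
#'
#' Rotating calipers: the minimum-area enclosing rectangle of a point set has
#' one side collinear with an edge of the convex hull, so it suffices to
#' sweep the hull edges, rotate the points into each edge frame and take the
#' smallest axis-aligned box.
#'
#' @inheritParams polygon_perimeter
#' @return list with `area`, `width`, `height`, `angle` (radians in `[0, pi)`
#'   of the rectangle side chosen as width).
#' @export
min_area_rect <- function(p) {
  hull <- convex_hull_polygon(p)
  n <- nrow(hull)
  if (n == 1) return(list(area = 0, width = 0, height = 0, angle = 0))
  if (n == 2) {
    d <- hull[2, ] - hull[1, ]
    return(list(area = 0, width = sqrt(sum(d^2)), height = 0,
                angle = atan2(d[2], d[1]) %% pi))
  }
  best <- list(area = Inf)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    wdt <- max(pu) - min(pu); hgt <- max(pv) - min(pv)
    a <- wdt * hgt
    if (a < best$area) {
      best <- list(area = a, width = wdt, height = hgt,
                   angle = atan2(u[2], u[1]) %% pi)
    }
  }
  best
}

#' Trace the outer contour of a mask
#'
#' Extracts the 0.5-level iso-boundary of the (zero-padded) mask with
#' marching squares. When the mask has several components or holes, the
#' contour enclosing the largest area is returned. The polygon is oriented
#' clockwise on screen and rotated to start at its topmost (then leftmost)
#' vertex.
#'
#' @param mask 0/1 matrix.
#' @return n x 2 matrix (columns x, y; 0-based sub-pixel coordinates).
#' @export
trace_contour <- function(mask) {
  m <- as_mask(mask)
  if (sum(m) == 0) stop("cannot trace contour of an empty mask", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  zp <- matrix(0, w + 2, h + 2)
  zp[2:(w + 1), 2:(h + 1)] <- t(m)
  cl <- grDevices::contourLines(x = -1:w, y = -1:h, z = zp, levels = 0.5)
  polys <- lapply(cl, function(s) as_contour(cbind(s$x, s$y)))
  areas <- vapply(polys, polygon_area, numeric(1))
  p <- polys[[which.max(areas)]]
  if (polygon_signed_area(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
  start <- order(p[, 2], p[, 1])[1]
  if (start > 1) p <- rbind(p[start:nrow(p), , drop = FALSE], p[1:(start - 1), , drop = FALSE])
  colnames(p) <- c("x", "y")
  p
}

#' Resample a closed contour to equal arc-length spacing
#'
#' @inheritParams polygon_perimeter
#' @param n number of output samples.
#' @return n x 2 matrix of points equally spaced along the closed contour.
#' @export
resample_contour <- function(p, n = 128L) {
  p <- as_contour(p)
  closed <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] - closed[-nrow(closed), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour (zero perimeter)", call. = FALSE)
  t_out <- seq(0, total, length.out = n + 1)[1:n]
  cbind(x = stats::approx(s, closed[, 1], xout = t_out)$y,
        y = stats::approx(s, closed[, 2], xout = t_out)$y)
}

# Simple-polygon check: no two non-adjacent edges intersect. O(n^2); used on
# resampled contours where n is small.
is_simple_polygon <- function(p) {
  p <- as_contour(p)
  n <- nrow(p)
  a <- p; b <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (length(js) == 0) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}
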