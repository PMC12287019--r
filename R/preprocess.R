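## Intensity preprocessing: neighbourhood spatial filtering and global
## histogram equalization.
##
## Images are integer matrices with values in [0, L-1] (default L = 256).
## The equalization mapping is the classic CDF construction:
##   CDF(i)      = sum_{j<=i} h(j)
##   CDF_norm(i) = CDF(i) / N
##   I_new(i)    = round(CDF_norm(i) * (L - 1))     (round half up)

#' Global histogram equalization
#'
#' Redistributes gray levels so the output cumulative histogram is
#' approximately linear, increasing global contrast and mitigating smooth
#' intensity inhomogeneity before thresholding and feature extraction.
#'
#' @param img integer matrix with values in `[0, L-1]`.
#' @param L number of representable gray levels (default 256).
#' @return A list with
#'   * `image`: the equalized image (same shape, values in `[0, L-1]`),
#'   * `map`: a `"vb_histmap"` list holding `h` (per-level counts), `cdf`,
#'     `cdf_norm` and `mapping` (level -> level lookup, 0-based levels).
#' @details The mapping is monotone non-decreasing, so gray-level order is
#'   preserved; applying equalization twice moves no pixel by more than one
#'   level (idempotence up to rounding).
#' @examples
#' eq <- equalize_histogram(matrix(c(0L, 0L, 255L, 255L), 2, 2, byrow = TRUE))
#' eq$image
#' @export
equalize_histogram <- function(img, L = 256L) {
  img <- as_gray(img, L)
  if (length(img) == 0) stop("image is empty", call. = FALSE)
  h <- tabulate(as.vector(img) + 1L, nbins = L)
  cdf <- cumsum(h)
  n <- length(img)
  cdf_norm <- cdf / n
  mapping <- as.integer(round_half_up(cdf_norm * (L - 1)))
  out <- matrix(mapping[img + 1L], nrow(img), ncol(img))
  map <- structure(
    list(h = h, cdf = cdf, cdf_norm = cdf_norm, mapping = mapping, L = L, n = n),
    class = "vb_histmap")
  list(image = as_gray(out, L), map = map)
}

#' Tiled adaptive histogram equalization
#'
#' Optional variant: the image is split into a grid of tiles, the CDF mapping
#' of [equalize_histogram()] is computed per tile, and each pixel is remapped
#' by bilinear interpolation between the mappings of the four surrounding
#' tile centres. Not part of the default pipeline.
#'
#' @inheritParams equalize_histogram
#' @param grid integer vector `c(ny, nx)` of tile counts.
#' @return The equalized image.
#' @export
equalize_adaptive <- function(img, grid = c(4L, 4L), L = 256L) {
  img <- as_gray(img, L)
  h <- nrow(img); w <- ncol(img)
  ny <- grid[1]; nx <- grid[2]
  ybr <- round(seq(0, h, length.out = ny + 1))
  xbr <- round(seq(0, w, length.out = nx + 1))
  maps <- array(0L, c(ny, nx, L))
  yc <- (head(ybr, -1) + ybr[-1] + 1) / 2   # tile centres, 1-based
  xc <- (head(xbr, -1) + xbr[-1] + 1) / 2
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    tile <- img[(ybr[i] + 1):ybr[i + 1], (xbr[j] + 1):xbr[j + 1], drop = FALSE]
    maps[i, j, ] <- equalize_histogram(tile, L)$map$mapping
  }
  iy <- pmin(pmax(findInterval(seq_len(h), yc), 1L), ny - 1L)
  ix <- pmin(pmax(findInterval(seq_len(w), xc), 1L), nx - 1L)
  if (ny == 1) iy <- rep(1L, h)
  if (nx == 1) ix <- rep(1L, w)
  wy <- if (ny > 1) pmin(pmax((seq_len(h) - yc[iy]) / (yc[iy + 1] - yc[iy]), 0), 1) else rep(0, h)
  wx <- if (nx > 1) pmin(pmax((seq_len(w) - xc[ix]) / (xc[ix + 1] - xc[ix]), 0), 1) else rep(0, w)
  out <- matrix(0L, h, w)
  for (x in seq_len(w)) {
    j <- ix[x]; jn <- min(j + 1L, nx)
    m00 <- maps[cbind(iy, j, img[, x] + 1L)]
    m10 <- maps[cbind(pmin(iy + 1L, ny), j, img[, x] + 1L)]
    m01 <- maps[cbind(iy, jn, img[, x] + 1L)]
    m11 <- maps[cbind(pmin(iy + 1L, ny), jn, img[, x] + 1L)]
    v <- (1 - wy) * ((1 - wx[x]) * m00 + wx[x] * m01) +
      wy * ((1 - wx[x]) * m10 + wx[x] * m11)
    out[, x] <- as.integer(round_half_up(v))
  }
  as_gray(out, L)
}

# 3x3 median via a pmin/pmax selection network (fast path).
median9 <- function(s) {
  mn <- function(a, b) pmin(a, b); mx <- function(a, b) pmax(a, b)
  p <- s
  sw <- function(i, j) { lo <- mn(p[[i]], p[[j]]); hi <- mx(p[[i]], p[[j]]); p[[i]] <<- lo; p[[j]] <<- hi }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(4, 7); sw(2, 5)
  sw(5, 8); sw(3, 6); sw(6, 9); sw(3, 5); sw(5, 7); sw(3, 5)
  p[[5]]
}

#' Neighbourhood spatial filtering
#'
#' Applies a `k x k` neighbourhood operator `g(x, y) = T[f(x, y)]` to every
#' pixel, with symmetric (reflect) padding at the edges.
#'
#' @param img integer gray matrix.
#' @param op `"median"`, `"mean"` or `"identity"`.
#' @param k odd neighbourhood width (ignored for `"identity"`).
#' @return Filtered integer image of the same shape. The mean filter rounds
#'   half up to stay on the integer gray scale; the median of an odd number
#'   of integers is itself an input value, so the median filter never
#'   introduces values absent from the input.
#' @export
spatial_filter <- function(img, op = c("median", "mean", "identity"), k = 3L) {
  op <- match.arg(op)
  img <- as_gray(img)
  if (op == "identity") return(img)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 1L) stop_field("k", "must be a positive odd integer")
  p <- k %/% 2L
  h <- nrow(img); w <- ncol(img)
  ridx <- c(p:1, 1:h, h:(h - p + 1))[1:(h + 2 * p)]
  cidx <- c(p:1, 1:w, w:(w - p + 1))[1:(w + 2 * p)]
  pad <- img[ridx, cidx, drop = FALSE]
  offs <- expand.grid(dy = 0:(k - 1), dx = 0:(k - 1))
  shifts <- lapply(seq_len(nrow(offs)), function(i) {
    pad[(1 + offs$dy[i]):(h + offs$dy[i]), (1 + offs$dx[i]):(w + offs$dx[i]), drop = FALSE]
  })
  out <- if (op == "mean") {
    round_half_up(Reduce(`+`, shifts) / (k * k))
  } else if (k == 3L) {
    median9(shifts)
  } else {
    arr <- do.call(cbind, lapply(shifts, as.vector))
    matrix(apply(arr, 1, stats::median), h, w)
  }
  as_gray(out)
}
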