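# Independent brute-force oracles used across the suite. These follow the
# set/equation definitions literally with explicit loops, deliberately
# sharing no code with the implementation they check.

# Dilation by set definition: z is foreground iff the reflected SE
# translated to z intersects A.
brute_dilate <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  off <- unclass(se)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- FALSE
    for (i in seq_len(nrow(off))) {
      rr <- r - off[i, "dy"]; cc <- c - off[i, "dx"]   # reflection: -b
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] == 1L) {
        hit <- TRUE; break
      }
    }
    out[r, c] <- as.integer(hit)
  }
  out
}

# Erosion by fit condition: z kept iff every translate of the SE lands on
# foreground (outside the image counts as background).
brute_erode <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  off <- unclass(se)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    fits <- TRUE
    for (i in seq_len(nrow(off))) {
      rr <- r + off[i, "dy"]; cc <- c + off[i, "dx"]
      if (rr < 1 || rr > h || cc < 1 || cc > w || mask[rr, cc] == 0L) {
        fits <- FALSE; break
      }
    }
    out[r, c] <- as.integer(fits)
  }
  out
}

# Convex-combination membership: q is in conv(P) iff it can be written as a
# convex combination of points of P; in the plane, iff some triple of points
# of P contains it (Caratheodory). Exhaustive over triples.
point_in_tri <- function(q, a, b, c) {
  s1 <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
  s2 <- (c[1] - b[1]) * (q[2] - b[2]) - (c[2] - b[2]) * (q[1] - b[1])
  s3 <- (a[1] - c[1]) * (q[2] - c[2]) - (a[2] - c[2]) * (q[1] - c[1])
  (s1 >= -1e-9 && s2 >= -1e-9 && s3 >= -1e-9) ||
    (s1 <= 1e-9 && s2 <= 1e-9 && s3 <= 1e-9)
}

brute_hull_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask == 1L)
  P <- cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
  out <- matrix(0L, h, w)
  n <- nrow(P)
  tri <- utils::combn(n, 3)
  ax <- P[tri[1, ], 1]; ay <- P[tri[1, ], 2]
  bx <- P[tri[2, ], 1]; by <- P[tri[2, ], 2]
  cx <- P[tri[3, ], 1]; cy <- P[tri[3, ], 2]
  # drop collinear (degenerate) triples: they span a segment, not a triangle,
  # and an all-zero sign test would wrongly capture the segment's whole line
  nd <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) > 1e-9
  ax <- ax[nd]; ay <- ay[nd]; bx <- bx[nd]; by <- by[nd]; cx <- cx[nd]; cy <- cy[nd]
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 1L) { out[r, c] <- 1L; next }
    qx <- c - 1L; qy <- r - 1L
    s1 <- (bx - ax) * (qy - ay) - (by - ay) * (qx - ax)
    s2 <- (cx - bx) * (qy - by) - (cy - by) * (qx - bx)
    s3 <- (ax - cx) * (qy - cy) - (ay - cy) * (qx - cx)
    inside <- (s1 >= -1e-9 & s2 >= -1e-9 & s3 >= -1e-9) |
      (s1 <= 1e-9 & s2 <= 1e-9 & s3 <= 1e-9)
    if (any(inside)) out[r, c] <- 1L
  }
  out
}

# KNN with explicit loops: distances, k nearest (ties by index), vote.
knn_oracle <- function(train_x, train_y, query, k) {
  m <- nrow(query)
  labels <- integer(m); post1 <- numeric(m)
  for (i in seq_len(m)) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      d[j] <- sqrt(sum((query[i, ] - train_x[j, ])^2))
    }
    nbr <- order(d, seq_along(d))[seq_len(k)]
    p1 <- mean(train_y[nbr] == 1L)
    post1[i] <- p1
    labels[i] <- if (p1 > 0.5) 1L else 0L
  }
  list(labels = labels, post1 = post1)
}

# Exact Wilcoxon two-sided p by literal enumeration of all 2^n sign vectors.
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Rasterized shapes for feature tests (0-based centre coordinates).
raster_disk <- function(r, pad = 3L) {
  n <- 2 * (r + pad) + 1
  cy <- r + pad
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  m <- matrix(as.integer((g$x - cy)^2 + (g$y - cy)^2 <= r^2), n, n)
  m
}

raster_ellipse <- function(a, b, pad = 3L) {
  n <- 2 * (max(a, b) + pad) + 1
  cc <- max(a, b) + pad
  g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  matrix(as.integer(((g$x - cc) / a)^2 + ((g$y - cc) / b)^2 <= 1), n, n)
}

random_mask <- function(h, w, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(rbinom(h * w, 1, p), h, w)
}

# A smooth random blob: a few dilated random seed points.
random_blob <- function(size = 40L, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, size, size)
  pts <- cbind(sample(15:(size - 15), 4, replace = TRUE),
               sample(15:(size - 15), 4, replace = TRUE))
  m[pts] <- 1L
  vbseg::dilate(m, vbseg::struct_element("disk", 8L))
}
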