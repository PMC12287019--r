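test_that("centroid equals the coordinate mean", {
  m <- matrix(0L, 10, 10); m[4, 8] <- 1L     # 0-based (x=7, y=3)
  expect_equal(region_centroid(m), c(gx = 7, gy = 3))
  sq <- matrix(0L, 8, 8); sq[1:4, 1:4] <- 1L
  expect_equal(region_centroid(sq), c(gx = 1.5, gy = 1.5))
  blob <- random_blob(seed = 3)
  idx <- which(blob == 1L)
  gx <- mean((idx - 1) %/% nrow(blob)); gy <- mean((idx - 1) %% nrow(blob))
  expect_equal(region_centroid(blob), c(gx = gx, gy = gy))
})

test_that("covariance eigenvalues give the expected eccentricities", {
  pa_disk <- principal_axes(raster_disk(20))
  expect_equal(pa_disk$eccentricity, 1, tolerance = 0.02)
  # 2:1 ellipse: continuum eigenvalue ratio (b/a)^2 = 0.25, major axis horizontal
  pa_ell <- principal_axes(raster_ellipse(40, 20))
  expect_equal(pa_ell$eccentricity, 0.25, tolerance = 0.02)
  expect_lt(min(pa_ell$angle, pi - pa_ell$angle), 0.02)
  expect_gte(pa_ell$lambda1, pa_ell$lambda2)
  # brute-force covariance oracle on a random blob
  blob <- random_blob(seed = 5)
  idx <- which(blob == 1L)
  x <- (idx - 1) %/% nrow(blob); y <- (idx - 1) %% nrow(blob)
  cxx <- mean((x - mean(x))^2); cyy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2))$values
  pa <- principal_axes(blob)
  expect_equal(pa$lambda1, max(ev), tolerance = 1e-12)
  expect_equal(pa$eccentricity, min(ev) / max(ev), tolerance = 1e-12)
  # 90-degree rotation (transpose) leaves eccentricity nearly unchanged
  expect_equal(principal_axes(t(blob))$eccentricity, pa$eccentricity,
               tolerance = 0.03)
  expect_error(principal_axes(matrix(c(1L, rep(0L, 8)), 3, 3)), "degenerate")
})

test_that("bending energy matches analytic curvature and its scaling law", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- function(r) cbind(r * cos(th) + 2 * r, r * sin(th) + 2 * r)
  be30 <- bending_energy(circ(30))
  expect_lt(abs(be30 - 1 / 900) / (1 / 900), 0.05)   # analytic K = 1/r
  be60 <- bending_energy(circ(60))
  expect_lt(abs(be60 - be30 / 4) / (be30 / 4), 0.02)
  # circle vs square of equal perimeter: the circle minimizes bending energy
  side <- 2 * pi * 30 / 4
  sq <- rbind(
    cbind(seq(0, side, length.out = 40), 0),
    cbind(side, seq(0, side, length.out = 40)),
    cbind(seq(side, 0, length.out = 40), side),
    cbind(0, seq(side, 0, length.out = 40)))
  sq <- sq[!duplicated(sq), ]
  expect_lt(be30, bending_energy(sq))
  expect_error(bending_energy(circ(30)[1:5, ]), "at least 8")
})

test_that("rectangularity hits its analytic values", {
  rect <- matrix(0L, 40, 60); rect[6:35, 6:55] <- 1L
  expect_equal(rectangularity(rect), 1, tolerance = 0.02)
  expect_equal(rectangularity(raster_disk(40)), pi / 4, tolerance = 0.02)
  # right triangle: minimum enclosing rectangle has twice the area
  n <- 120
  tri <- matrix(0L, n + 10, n + 10)
  for (i in 1:n) tri[i + 4, 5:(4 + n - i + 1)] <- 1L
  expect_equal(rectangularity(tri), 0.5, tolerance = 0.03)
})

test_that("convexity is 1 for convex shapes and detects concavity exactly", {
  hexagon <- cbind(c(2, 6, 8, 6, 2, 0), c(0, 0, 3, 6, 6, 3))
  expect_equal(convexity(hexagon), 1, tolerance = 1e-9)
  # plus sign with unit arms: hull perimeter computed by hand
  plus <- cbind(
    c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
    c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
  hull_perim <- 4 * (1 + sqrt(2))       # octagon over the 12-gon
  expect_equal(convexity(plus), hull_perim / 12, tolerance = 1e-9)
  for (s in 1:5) {
    p <- trace_contour(random_blob(seed = s + 40))
    expect_lte(convexity(p), 1 + 1e-9)
  }
})

test_that("Euler number counts components minus holes", {
  solid <- matrix(0L, 8, 8); solid[2:6, 2:6] <- 1L
  expect_equal(euler_number(solid), 1L)
  ring <- solid; ring[3:5, 3:5] <- 0L
  expect_equal(euler_number(ring), 0L)
  two <- matrix(0L, 12, 24)
  two[2:10, 2:10] <- 1L; two[3:5, 3:5] <- 0L; two[7:9, 7:9] <- 0L  # 2 holes
  two[4:8, 14:20] <- 1L
  expect_equal(euler_number(two), 0L)   # S = 2, N = 2
})

test_that("profiles are the row/column counts over the bounding box", {
  rect <- matrix(0L, 9, 9); rect[3:5, 2:6] <- 1L
  pr <- profiles(rect)
  expect_equal(pr$x, rep(3L, 5))
  expect_equal(pr$y, rep(5L, 3))
  tri <- matrix(0L, 8, 8)
  for (i in 1:4) tri[i + 1, 2:(2 + 4 - i)] <- 1L
  prt <- profiles(tri)
  expect_equal(prt$y, c(4L, 3L, 2L, 1L))
  expect_equal(prt$x, c(4L, 3L, 2L, 1L))
  for (s in 1:4) {
    b <- random_blob(seed = s + 50)
    p <- profiles(b)
    expect_equal(sum(p$x), sum(b))
    expect_equal(sum(p$y), sum(b))
  }
})

test_that("shape descriptors are exactly translation invariant", {
  blob <- random_blob(seed = 6)
  big <- matrix(0L, 70, 70); big[10:49, 10:49] <- blob
  shifted <- matrix(0L, 70, 70); shifted[21:60, 16:55] <- blob
  f1 <- extract_features(big * 100L, big)
  f2 <- extract_features(shifted * 100L, shifted)
  expect_equal(f1$eccentricity, f2$eccentricity)
  expect_equal(f1$rectangularity, f2$rectangularity)
  expect_equal(f1$convexity, f2$convexity)
  expect_equal(f1$euler_number, f2$euler_number)
  expect_equal(f1$bending_energy, f2$bending_energy)
  expect_equal(f1$profile_x, f2$profile_x)
})

test_that("descriptors are scale invariant and bending energy scales as 1/s^2", {
  small <- raster_disk(30); large <- raster_disk(60)
  fs <- extract_features(small * 100L, small)
  fl <- extract_features(large * 100L, large)
  expect_lt(abs(fs$eccentricity - fl$eccentricity), 0.03)
  expect_lt(abs(fs$rectangularity - fl$rectangularity), 0.03)
  expect_lt(abs(fs$convexity - fl$convexity), 0.03)
  expect_lt(abs(fl$bending_energy - fs$bending_energy / 4) / (fs$bending_energy / 4), 0.05)
})

test_that("rotation by 15 degrees moves the rotation-robust descriptors little", {
  # rasterize the same smooth ellipse at 0 and 15 degrees
  raster_rot_ellipse <- function(a, b, deg) {
    th <- deg * pi / 180
    n <- 2 * (max(a, b) + 4) + 1; cc <- max(a, b) + 4
    g <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
    u <- cos(th) * (g$x - cc) + sin(th) * (g$y - cc)
    v <- -sin(th) * (g$x - cc) + cos(th) * (g$y - cc)
    matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), n, n)
  }
  blob <- raster_rot_ellipse(18, 11, 0)
  rot <- raster_rot_ellipse(18, 11, 15)
  f0 <- extract_features(blob * 120L, blob)
  f1 <- extract_features(rot * 120L, rot)
  expect_lt(abs(f0$eccentricity - f1$eccentricity), 0.05)
  expect_lt(abs(f0$rectangularity - f1$rectangularity), 0.05)
  expect_lt(abs(f0$convexity - f1$convexity), 0.05)
})

test_that("wedge-compressed vertebrae separate from normals in eccentricity", {
  spec <- phantom_spec(noise_sd = 5, bias_amplitude = 0.1,
                       height_loss_fraction = 0.4)
  ds <- generate_dataset(spec, n_cases = 14, fracture_prevalence = 0.5, seed = 31)
  ecc <- list(normal = c(), fractured = c())
  for (case in ds$cases) {
    for (lv in names(case$truth_masks)) {
      e <- principal_axes(case$truth_masks[[lv]])$eccentricity
      key <- if (case$labels[[lv]] == 1L) "fractured" else "normal"
      ecc[[key]] <- c(ecc[[key]], e)
    }
  }
  pooled_sd <- sqrt((stats::var(ecc$normal) + stats::var(ecc$fractured)) / 2)
  d <- abs(mean(ecc$normal) - mean(ecc$fractured)) / pooled_sd
  expect_gt(d, 1)
})

test_that("the feature vector has a fixed, documented layout", {
  blob <- random_blob(seed = 8)
  f <- extract_features(blob * 90L, blob)
  v <- feature_vector(f)
  expect_equal(names(v)[1:6],
               c("area", "eccentricity", "rectangularity", "convexity",
                 "euler", "bending_energy"))
  expect_equal(length(v), 6 + 8 + 4)
  expect_equal(length(feature_vector(f, blocks = "shape")), 6)
  expect_equal(length(feature_vector(f, blocks = c("shape", "intensity"))), 10)
})
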