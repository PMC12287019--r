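test_that("dilation and erosion match the set-definition oracle", {
  ses <- list(struct_element("square", 1), struct_element("disk", 1),
              struct_element("disk", 2), struct_element("square", 2))
  sizes <- list(c(5, 5), c(8, 6), c(12, 12), c(9, 12))
  s <- 0
  for (se in ses) for (sz in sizes) {
    s <- s + 1
    m <- random_mask(sz[1], sz[2], p = 0.35, seed = s)
    expect_identical(dilate(m, se), brute_dilate(m, se))
    expect_identical(erode(m, se), brute_erode(m, se))
  }
  # structured edge cases
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  d <- dilate(single, struct_element("square", 1))
  expect_equal(sum(d), 9); expect_true(all(d[2:4, 2:4] == 1L))
  expect_identical(erode(d, struct_element("square", 1)), single)
  empty <- matrix(0L, 6, 6)
  expect_identical(dilate(empty, struct_element("disk", 2)), empty)
  full <- matrix(1L, 8, 8)
  er <- erode(full, struct_element("square", 1))
  expect_true(all(er[2:7, 2:7] == 1L))
  expect_true(all(er[1, ] == 0L) && all(er[, 1] == 0L))
})

test_that("erosion is the complement-dual of dilation", {
  se <- struct_element("disk", 2)    # symmetric, equals its reflection
  for (s in 1:5) {
    m <- random_mask(16, 16, p = 0.5, seed = s + 10)
    expect_identical(erode(m, se), 1L - dilate(1L - m, se))
  }
})

test_that("opening is anti-extensive, closing extensive, both idempotent", {
  # closing extensivity requires the dilated set to stay inside the image
  # (out-of-image pixels count as background for the erosion step), so the
  # random content is kept away from the border by a margin > SE radius
  se <- struct_element("disk", 1)
  for (s in 1:5) {
    m <- matrix(0L, 18, 18)
    m[3:16, 3:16] <- random_mask(14, 14, p = 0.45, seed = s + 20)
    op <- morph_open(m, se); cl <- morph_close(m, se)
    expect_true(all(op <= m))
    expect_true(all(cl >= m))
    expect_identical(morph_open(op, se), op)
    expect_identical(morph_close(cl, se), cl)
  }
})

test_that("hole filling fills enclosed background only", {
  ring <- matrix(0L, 9, 9)
  ring[3:7, 3:7] <- 1L; ring[4:6, 4:6] <- 0L
  filled <- fill_holes(ring)
  expect_true(all(filled[3:7, 3:7] == 1L))
  expect_equal(sum(filled), 25)
  solid <- matrix(0L, 7, 7); solid[2:5, 2:5] <- 1L
  expect_identical(fill_holes(solid), solid)
  # nested rings: everything enclosed by the outer ring becomes foreground
  nest <- matrix(0L, 15, 15)
  nest[2:14, 2:14] <- 1L; nest[3:13, 3:13] <- 0L   # outer ring
  nest[5:11, 5:11] <- 1L; nest[6:10, 6:10] <- 0L   # inner ring
  expect_true(all(fill_holes(nest)[2:14, 2:14] == 1L))
})

test_that("border clearing removes exactly the border-touching components", {
  m <- matrix(0L, 10, 10)
  m[1:3, 4:6] <- 1L        # touches the top row
  m[5:7, 2:4] <- 1L        # interior
  m[8:10, 8:10] <- 1L      # touches the bottom-right corner
  out <- clear_border(m)
  expect_equal(sum(out), 9)
  expect_true(all(out[5:7, 2:4] == 1L))
  interior <- matrix(0L, 8, 8); interior[3:5, 3:5] <- 1L
  expect_identical(clear_border(interior), interior)
})

test_that("component filtering enforces island size and centroid alignment", {
  m <- matrix(0L, 20, 40)
  m[3:8, 10:20] <- 1L                 # large component
  m[15, 12:13] <- 1L                  # 2-pixel speck
  out <- filter_components(m, min_area_fraction = 0.1, centroid_band_fraction = 1)
  expect_equal(sum(out), 6 * 11)
  # five aligned blobs plus one far to the right
  m2 <- matrix(0L, 60, 100)
  for (i in 0:4) m2[(4 + i * 11):(9 + i * 11), 40:55] <- 1L
  m2[20:25, 85:98] <- 1L
  out2 <- filter_components(m2, min_area_fraction = 0.05,
                            centroid_band_fraction = 0.15)
  expect_equal(max(vbseg:::label_components(out2, 8L)), 5)
  expect_true(all(out2[, 85:98] == 0L))
  # a lone component survives any band: its centroid is the median
  lone <- matrix(0L, 10, 10); lone[2:4, 7:9] <- 1L
  expect_identical(filter_components(lone, 0.5, 0.01), lone)
  expect_error(filter_components(matrix(0L, 5, 5)), "no components")
})

test_that("convex hull regions match the convex-combination oracle", {
  # L-shaped (notched) component
  L <- matrix(0L, 12, 12)
  L[3:9, 3:5] <- 1L; L[7:9, 3:9] <- 1L
  expect_identical(convex_hull_regions(L), brute_hull_mask(L))
  # solid rectangle is already convex
  rect <- matrix(0L, 10, 14); rect[3:7, 4:11] <- 1L
  expect_identical(convex_hull_regions(rect), rect)
  # sparse random component on a small grid
  set.seed(4)
  sp <- matrix(0L, 13, 13)
  sp[cbind(sample(2:12, 8, TRUE), sample(2:12, 8, TRUE))] <- 1L
  sp <- dilate(sp, struct_element("square", 1))   # make it connected enough
  lab <- vbseg:::label_components(sp, 8L)
  big <- (lab == 1L) * 1L
  expect_identical(convex_hull_regions(big), brute_hull_mask(big))
})

test_that("convexification never loses area, per component", {
  for (s in 1:5) {
    m <- random_mask(15, 15, p = 0.2, seed = s + 30)
    out <- convex_hull_regions(m)
    expect_true(all(out >= m))
  }
})
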