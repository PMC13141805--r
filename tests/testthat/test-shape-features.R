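test_that("connectivity conventions match their definitions", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(extract_regions(m, connectivity = 8)), 1)
  expect_equal(nrow(extract_regions(m, connectivity = 4)), 2)
  expect_equal(nrow(extract_regions(matrix(FALSE, 4, 4))), 0)
})

test_that("interior holes are filled before feature computation", {
  ring <- disc_mask(80, 30) & !disc_mask(80, 15)
  regs <- extract_regions(ring)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$n_pixels[1], sum(disc_mask(80, 30)))
  # debris inside the lumen is absorbed into the same region
  ring2 <- ring | disc_mask(80, 3)
  expect_equal(nrow(extract_regions(ring2)), 1)
})

test_that("label counts agree with an independent flood-fill oracle", {
  # extract_regions fills interior holes before labeling, so the oracle is a
  # BFS hole-fill followed by a BFS component count — a fully independent path
  for (seed in c(3, 17, 99)) {
    set.seed(seed)
    m <- matrix(runif(50 * 50) < 0.35, 50, 50)
    for (conn in c(4, 8)) {
      expect_equal(nrow(extract_regions(m, conn)),
                   flood_count(oracle_fill(m, conn), conn),
                   info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("labels come in deterministic scanline order", {
  m <- matrix(FALSE, 20, 20)
  m[15:17, 2:4] <- TRUE     # lower-left block
  m[2:4, 15:17] <- TRUE     # upper-right block (topmost pixel first)
  regs <- extract_regions(m)
  expect_equal(regs$label, c(1L, 2L))
  expect_lt(regs$centroid_row[1], regs$centroid_row[2])
})

test_that("a rasterized disc hits the analytic unit anchors", {
  f <- region_features(disc_mask(130, 50), mpp = 1)
  for (col in c("roundness", "circularity", "compactness", "convexity",
                "anisometry")) {
    expect_equal(f[[col]], 1, tolerance = 0.02, info = col)
  }
  expect_equal(f$area_um2, sum(disc_mask(130, 50)))
})

test_that("square and 2:1 ellipse match their closed forms", {
  fsq <- region_features(rect_mask(130, 16:115, 16:115), mpp = 1)
  expect_equal(fsq$compactness, 4 / pi, tolerance = 0.03)
  expect_equal(fsq$circularity, 2 / pi, tolerance = 0.03)

  fel <- region_features(ellipse_mask(140, 55, 27.5), mpp = 1)
  expect_equal(fel$anisometry, 2, tolerance = 0.02)
  expect_equal(fel$convexity, 1, tolerance = 0.02)
})

test_that("degenerate regions take guard values", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  f <- region_features(m, mpp = 2)
  expect_equal(f$area_um2, 4)
  expect_equal(f$roundness, 1)
  expect_equal(f$circularity, 1)
  expect_equal(f$compactness, 1)
  expect_equal(f$anisometry, 1)
})

test_that("pixel area equals a brute-force count at any mpp", {
  set.seed(41)
  blob <- disc_mask(60, 12, c(25, 30)) | ellipse_mask(60, 18, 7, c(35, 30), 0.6)
  f <- region_features(blob, mpp = 0.7)
  expect_equal(f$area_um2, sum(blob) * 0.7^2)
  expect_equal(f$equivalent_diameter_um, 2 * 0.7 * sqrt(sum(blob) / pi))
})

test_that("dimensionless descriptors are invariant to placement and scale", {
  base <- ellipse_mask(120, 30, 18, c(50, 55), 0.4)
  shifted <- ellipse_mask(120, 30, 18, c(70, 60), 0.4)
  fb <- region_features(base, 1)
  fs <- region_features(shifted, 1)
  cols <- c("roundness", "circularity", "compactness", "convexity",
            "anisometry")
  for (col in cols) {
    expect_equal(fs[[col]], fb[[col]], tolerance = 0.01,
                 info = paste("translation", col))
  }
  rotated <- ellipse_mask(120, 30, 18, c(50, 55), 0.4 + pi / 2)
  fr <- region_features(rotated, 1)
  scaled <- ellipse_mask(240, 60, 36, c(100, 110), 0.4)
  f2 <- region_features(scaled, 1)
  for (col in cols) {
    expect_equal(fr[[col]], fb[[col]], tolerance = 0.03,
                 info = paste("rotation", col))
    expect_equal(f2[[col]], fb[[col]], tolerance = 0.03,
                 info = paste("scaling", col))
  }
})

test_that("stretching an ellipse moves the descriptors monotonically", {
  ratios <- c(1, 1.5, 2, 3)
  f <- lapply(ratios, function(r) {
    region_features(ellipse_mask(160, 25 * sqrt(r), 25 / sqrt(r)), 1)
  })
  anis <- vapply(f, `[[`, numeric(1), "anisometry")
  comp <- vapply(f, `[[`, numeric(1), "compactness")
  rnd <- vapply(f, `[[`, numeric(1), "roundness")
  expect_true(all(diff(anis) > 0))
  expect_true(all(diff(comp) > 0))
  expect_true(all(diff(rnd) < 0))
})

test_that("convexity flags concave shapes", {
  u <- rect_mask(80, 20:60, 20:30) | rect_mask(80, 20:60, 50:60) |
    rect_mask(80, 50:60, 20:60)
  fu <- region_features(u, 1)
  expect_lt(fu$convexity, 0.85)
  expect_equal(region_features(rect_mask(80, 20:60, 20:60), 1)$convexity, 1,
               tolerance = 0.02)
})

test_that("border-touching regions are flagged", {
  m <- matrix(FALSE, 30, 30)
  m[1:5, 10:14] <- TRUE
  m[15:19, 10:14] <- TRUE
  regs <- extract_regions(m)
  expect_identical(regs$touches_border, c(TRUE, FALSE))
})
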