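test_that("PNG write/read round trip is pixel-exact", {
  set.seed(11)
  px <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), dim = c(64, 64, 3))
  s <- slide_image(px, mpp = 1)
  f <- withr::local_tempfile(fileext = ".png")
  write_slide_png(s, f)
  rt <- read_slide(f)
  expect_identical(round(rt$pixels), px * 1.0)
  expect_true(rt$mpp_assumed)
})

test_that("unreadable inputs raise format errors naming the path", {
  expect_error(read_slide("/nonexistent/slide.png"),
               "not found", class = "steatr_error_format")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", f)
  expect_error(read_slide(f), class = "steatr_error_format")
  g <- withr::local_tempfile(fileext = ".png")
  writeLines("junk", g)
  expect_error(read_slide(g), class = "steatr_error_format")
})

test_that("embedded mpp metadata is honored and invalid metadata falls back", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_minimal_tiff(f, description = "Aperio Image Library|MPP = 0.499|")
  m <- read_mpp(f)
  expect_equal(m$mpp, 0.499)
  expect_false(m$assumed)

  # resolution tags: 20080 px/cm -> 10000/20080 um/px
  g <- withr::local_tempfile(fileext = ".tif")
  write_minimal_tiff(g, xres = 20080, res_unit = "cm")
  mg <- read_mpp(g)
  expect_equal(mg$mpp, 10000 / 20080, tolerance = 1e-6)
  expect_false(mg$assumed)

  # zero/negative embedded value is treated as absent
  h <- withr::local_tempfile(fileext = ".tif")
  write_minimal_tiff(h, description = "MPP = 0")
  mh <- read_mpp(h)
  expect_equal(mh$mpp, 0.249)
  expect_true(mh$assumed)

  # plain PNG has no metadata: scanner-default fallback, flagged
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, dim = c(4, 4, 3)), p)
  mp <- read_mpp(p)
  expect_equal(mp$mpp, 0.249)
  expect_true(mp$assumed)
})

test_that("pyramid levels scale mpp by the downsample factor", {
  f <- withr::local_tempfile(fileext = ".tif")
  base <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  tiff::writeTIFF(list(base, base[seq(1, 64, 4), seq(1, 64, 4), ]), f)
  s0 <- read_slide(f, level = 0)
  s1 <- read_slide(f, level = 1)
  expect_equal(s1$mpp / s0$mpp, 4)
  expect_equal(s1$mpp, 0.249 * 4)
  err <- tryCatch(read_slide(f, level = 5), error = identity)
  expect_s3_class(err, "steatr_error_level")
  expect_match(conditionMessage(err), "available levels: 0, 1")
})

test_that("overlays alter exactly the masked pixels", {
  set.seed(21)
  px <- array(sample(40:200, 50 * 50 * 3, replace = TRUE), dim = c(50, 50, 3))
  s <- slide_image(px, mpp = 1)
  none <- matrix(FALSE, 50, 50)

  f <- withr::local_tempfile(fileext = ".png")
  write_overlay(s, none, none, f)
  expect_identical(round(read_slide(f)$pixels), px * 1.0)

  # saturation case: full accepted mask at blend 1 -> pure green
  full <- matrix(TRUE, 50, 50)
  write_overlay(s, full, none, f, blend = 1)
  out <- round(read_slide(f)$pixels)
  expect_true(all(out[, , 1] == 0 & out[, , 2] == 255 & out[, , 3] == 0))

  # pixel-diff set equals the union of the masks
  acc <- disc_mask(50, 8, c(20, 20))
  rej <- disc_mask(50, 5, c(38, 36))
  write_overlay(s, acc, rej, f, blend = 0.6)
  out <- round(read_slide(f)$pixels)
  changed <- apply(out != px, c(1, 2), any)
  expect_true(all(changed[acc | rej]))
  expect_false(any(changed & !(acc | rej)))

  expect_error(write_overlay(s, matrix(FALSE, 10, 10), none, f),
               class = "steatr_error_geometry")
})

test_that("downsampling halves geometry and doubles mpp", {
  s <- flat_slide(64, c(100, 150, 200), mpp = 0.5)
  d <- downsample_slide(s, 2)
  expect_equal(dim(d), c(32L, 32L))
  expect_equal(d$mpp, 1.0)
  expect_equal(d$pixels[1, 1, 2], 150)
})
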