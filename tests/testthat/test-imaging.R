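test_that("rasterization is exact on axis-aligned rectangles and degenerate shapes", {
  rect <- cbind(c(2, 8, 8, 2), c(1, 1, 5, 5))
  mask <- rasterize_body_contour(rect, c(8, 10))
  expect_identical(sum(mask), 24L)  # 6 x 4 pixel block
  # pixel centers: rows 2..5, cols 3..8
  expect_true(all(mask[2:5, 3:8]))

  flat <- cbind(c(1, 5, 9), c(3, 3, 3))
  expect_identical(sum(rasterize_body_contour(flat, c(8, 10))), 0L)
  expect_error(rasterize_body_contour(cbind(1:2, 1:2), c(8, 8)),
               class = "zfpk_invalid_polygon")
})

test_that("rasterized area tracks the shoelace area for random convex polygons", {
  shoelace <- function(v) {
    x <- v[, 1]; y <- v[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  set.seed(41)
  for (i in 1:20) {
    # convex polygon: hull of random points, scaled into the frame
    pts <- cbind(runif(12, 10, 54), runif(12, 10, 54))
    hull <- pts[chull(pts), ]
    if (shoelace(hull) < 20) next
    mask <- rasterize_body_contour(hull, c(64, 64))
    # a convex region's pixel count deviates from its area by at most
    # roughly its perimeter; one pixel-row of slack per edge direction
    perim <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ])^2)))
    expect_lt(abs(sum(mask) - shoelace(hull)), perim)
  }
})

test_that("integrated intensity is a masked pixel sum with additivity", {
  set.seed(43)
  px <- matrix(runif(64 * 64, 0, 100), 64, 64)
  img <- masked_image(px)
  # brute-force double loop over every pixel
  acc <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) acc <- acc + px[i, j]
  expect_equal(integrated_intensity(img), acc)

  m1 <- matrix(FALSE, 64, 64); m1[1:32, ] <- TRUE
  m2 <- !m1
  expect_equal(integrated_intensity(masked_image(px, m1)) +
                 integrated_intensity(masked_image(px, m2)),
               integrated_intensity(img))
  # uniform value over k pixels
  u <- masked_image(matrix(7, 64, 64), m1)
  expect_equal(integrated_intensity(u), 7 * sum(m1))
  expect_warning(empty <- integrated_intensity(
    masked_image(px, matrix(FALSE, 64, 64))), class = "zfpk_empty_mask")
  expect_identical(empty, 0)
})

test_that("exposure correction is linear and round-trips", {
  expect_equal(exposure_correction(1000, 50, 50), 1000)
  expect_equal(exposure_correction(1000, 25, 50), 2000)
  corrected <- exposure_correction(1234, 80, 20)
  expect_equal(exposure_correction(corrected, 20, 80), 1234)
  expect_error(exposure_correction(10, 0, 50), class = "zfpk_invalid_input")
})

test_that("the synthetic embryo closes the loop from pixels to amount", {
  # noiseless: masked sum is exactly fluor * amount
  r <- render_synthetic_embryo(0.5, 2000, background = 0, seed = 1)
  expect_equal(integrated_intensity(r$image), 1000)
  # deterministic per seed
  r2 <- render_synthetic_embryo(0.5, 2000, background = 5, seed = 1)
  r3 <- render_synthetic_embryo(0.5, 2000, background = 5, seed = 1)
  expect_identical(r2$image$pixels, r3$image$pixels)
  # re-rasterizing the ground-truth contour reproduces the image mask
  expect_identical(rasterize_body_contour(r$contour, dim(r$image$pixels)),
                   r$image$mask)

  # with background: background-corrected masked sum within 3 sigma
  hits <- 0
  for (s in 1:20) {
    rb <- render_synthetic_embryo(0.5, 2000, background = 10, seed = s)
    k <- sum(rb$image$mask)
    tot <- integrated_intensity(rb$image) - k * 10
    if (abs(tot - 1000) <= 3 * sqrt(k * 10)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("grayscale image files round-trip at their bit depth", {
  set.seed(47)
  px <- matrix(sample(0:65535, 32 * 64), 64, 32)
  # enforce a saturated pixel to exercise the flag
  px[1, 1] <- 65535

  # TIFF is 16-bit: lossless
  path <- tempfile(fileext = ".tiff")
  write_gray_image(px, path)
  back <- read_gray_image(path)
  expect_equal(unclass(back)[seq_along(px)], as.vector(px))
  expect_gte(attr(back, "saturated"), 1)
  unlink(path)

  # PNG is 8-bit: exact up to one quantisation step on the 16-bit scale
  path <- tempfile(fileext = ".png")
  write_gray_image(px, path)
  back <- read_gray_image(path)
  expect_lt(max(abs(unclass(back)[seq_along(px)] - as.vector(px))), 130)
  expect_gte(attr(back, "saturated"), 1)
  unlink(path)
})
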