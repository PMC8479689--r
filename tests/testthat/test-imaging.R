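test_that("moment-based geometry recovers an analytic pixel disc", {
  mask <- disc_mask(50)
  g <- measure_geometry(mask, pixel_size = 0.05)
  expect_equal(g$area, sum(mask) * 0.05^2)
  expect_lt(abs(g$area - pi * (50 * 0.05)^2) / (pi * 2.5^2), 0.02)
  expect_lt(abs(g$r_equiv - 2.5) / 2.5, 0.01)
  expect_lt(g$r_max / g$r_min, 1.02)
})

test_that("single-pixel mask is degenerate but defined", {
  mask <- matrix(FALSE, 5, 5); mask[3, 3] <- TRUE
  g <- measure_geometry(mask, pixel_size = 0.05)
  expect_equal(g$area, 0.05^2)
  expect_equal(g$r_max, g$r_min)
  expect_error(measure_geometry(matrix(FALSE, 5, 5), pixel_size = 0.05),
               "empty")
})

test_that("render is deterministic and reproduces the requested shape", {
  im1 <- render_cell(3, 2, orientation = 0.4, pixel_size = 0.05,
                     image_size = 160, noise_sd = 0.05, seed = 11)
  im2 <- render_cell(3, 2, orientation = 0.4, pixel_size = 0.05,
                     image_size = 160, noise_sd = 0.05, seed = 11)
  expect_identical(im1$pixels, im2$pixels)
  # noiseless (60, 40) px ellipse: mask axis ratio 1.5 within 2%
  im <- render_cell(3, 2, pixel_size = 0.05, image_size = 160,
                    noise_sd = 0, seed = 1)
  mask <- im$pixels > 0.5
  g <- measure_geometry(mask, 0.05)
  expect_lt(abs(g$r_max / g$r_min - 1.5), 0.03)
  expect_error(render_cell(5, 4, pixel_size = 0.05, image_size = 100),
               "frame")
  expect_error(render_cell(0.05, 0.05, pixel_size = 0.05,
                           image_size = 100), ">= 2 px")
})

test_that("segmentation thresholds, keeps the largest component, fills holes", {
  im <- render_cell(2.5, 2.5, pixel_size = 0.05, image_size = 128,
                    noise_sd = 0, seed = 1)
  mask <- segment_cell(im)
  expect_lt(abs(sum(mask) - pi * 50^2) / (pi * 50^2), 0.02)
  # uniform image: segmentation failure
  expect_error(segment_cell(cell_image(matrix(0.5, 32, 32), 0.05)),
               "segmentation failure")
  # two discs: only the larger survives
  two <- matrix(0, 200, 200)
  two[as.logical(disc_mask(40, 200))] <- 1
  small <- disc_mask(10, 41)
  two[10:50, 150:190][small] <- 1
  mask2 <- segment_cell(cell_image(two, 0.05))
  expect_lt(abs(sum(mask2) - pi * 40^2) / (pi * 40^2), 0.02)
  # holes are filled
  holed <- matrix(0, 128, 128)
  holed[as.logical(disc_mask(40, 128))] <- 1
  holed[60:68, 60:68] <- 0
  mask3 <- segment_cell(cell_image(holed, 0.05))
  expect_true(all(mask3[60:68, 60:68]))
})

test_that("render-segment-measure round-trips noiseless ellipses within 2%", {
  for (r in c(2, 4, 8)) {
    for (ratio in c(1, 1.5, 2)) {
      a <- r * sqrt(ratio); b <- r / sqrt(ratio)
      im <- render_cell(a, b, orientation = 0.7, pixel_size = 0.05,
                        image_size = 2 * ceiling(a / 0.05) + 32,
                        noise_sd = 0, seed = 3)
      g <- measure_geometry(segment_cell(im))
      expect_lt(abs(g$r_max - a) / a, 0.02)
      expect_lt(abs(g$r_min - b) / b, 0.02)
      expect_lt(abs(g$area - pi * a * b) / (pi * a * b), 0.02)
    }
  }
})

test_that("ellipse axes and orientation recovered from analytic moments", {
  im <- render_cell(6, 4, orientation = 0.5, pixel_size = 0.05,
                    image_size = 300, noise_sd = 0, seed = 1)
  g <- measure_geometry(segment_cell(im))
  expect_lt(abs(g$r_max - 6) / 6, 0.02)
  expect_lt(abs(g$r_min - 4) / 4, 0.02)
  ang <- abs(g$orientation - 0.5) %% pi
  expect_lt(min(ang, pi - ang), 2 * pi / 180)
})

test_that("measurement is invariant under a 90-degree image rotation", {
  im <- render_cell(5, 3, orientation = 0.3, pixel_size = 0.05,
                    image_size = 256, noise_sd = 0.03, seed = 5)
  g1 <- measure_geometry(segment_cell(im))
  rot <- cell_image(t(im$pixels)[ncol(im$pixels):1, ], im$pixel_size)
  g2 <- measure_geometry(segment_cell(rot))
  expect_equal(g1$area, g2$area, tolerance = 1e-12)
  expect_equal(g1$r_max / g1$r_min, g2$r_max / g2$r_min,
               tolerance = 1e-10)
})

test_that("moderate pixel noise biases the equivalent radius by < 3%", {
  im <- render_cell(2.5, 2.5, pixel_size = 0.05, image_size = 160,
                    noise_sd = 0.10, seed = 21)
  g <- measure_geometry(segment_cell(im))
  expect_lt(abs(g$r_equiv - 2.5) / 2.5, 0.03)
})
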