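flat_image <- function(rgb, h = 40, w = 60, pixel_size_mm = 0.2) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  raster_image(px, pixel_size_mm)
}

noisy_image <- function(seed, h = 80, w = 120, mean = c(180, 170, 160),
                        sd = 15) {
  set.seed(seed)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rnorm(h * w, mean[ch], sd)
  raster_image(px, 0.2)
}

test_that("white balance neutralizes the patch at unchanged luminance", {
  img <- noisy_image(1, mean = c(200, 180, 160), sd = 4)
  patch <- patch_region(10, 10, 25, 25)
  pp_before <- blockface:::patch_pixels(img, patch)
  out <- white_balance(img, patch)
  pp <- blockface:::patch_pixels(out, patch)
  m <- colMeans(pp)
  expect_lt(max(m) - min(m), 1)                       # neutral
  # overall patch brightness (mean of channel means) is preserved
  expect_lt(abs(mean(pp) - mean(pp_before)), 1)
  # gains for patch means (200, 180, 160) are (0.9, 1.0, 1.125)
  exact <- flat_image(c(200, 180, 160))
  outf <- white_balance(exact, patch_region(0, 0, 25, 25))
  expect_equal(outf$pixels[1, 1, ], blockface:::quantize8(c(200, 180, 160) *
                                                c(0.9, 1.0, 1.125)) * 1L,
               ignore_attr = TRUE)
})

test_that("white balance is idempotent and a neutral patch is a no-op", {
  neutral <- noisy_image(2, mean = c(180, 180, 180), sd = 0.01)
  patch <- patch_region(5, 5, 25, 25)
  expect_identical(white_balance(neutral, patch)$pixels, neutral$pixels)
  img <- noisy_image(3, mean = c(200, 180, 160), sd = 3)
  once <- white_balance(img, patch)
  twice <- white_balance(once, patch)
  expect_lte(max(abs(twice$pixels - once$pixels)), 1)
})

test_that("white balance rejects a black patch and warns off-paraffin", {
  black <- flat_image(c(0, 0, 0))
  expect_error(white_balance(black, patch_region(0, 0, 10, 10)), "black")
  textured <- noisy_image(4, sd = 40)
  expect_warning(white_balance(textured, patch_region(0, 0, 25, 25)),
                 "paraffin")
  expect_error(white_balance(flat_image(c(100, 100, 100)),
                             patch_region(50, 0, 25, 25)), "outside")
})

test_that("colour enhancement has exact identity, desaturation and doubling", {
  img <- noisy_image(5)
  expect_identical(enhance_color(img, 1)$pixels, img$pixels)
  gray <- enhance_color(img, 0)$pixels
  expect_lte(max(abs(gray[, , 1] - gray[, , 2])), 1)
  expect_lte(max(abs(gray[, , 2] - gray[, , 3])), 1)
  # hand-computed single pixel: luminance of (120, 100, 80) is 103.72
  px <- flat_image(c(120, 100, 80))
  lum <- 0.299 * 120 + 0.587 * 100 + 0.114 * 80
  out <- enhance_color(px, 2)
  expect_equal(out$pixels[1, 1, ], blockface:::quantize8(lum + 2 * (c(120, 100, 80) - lum)) * 1L,
               ignore_attr = TRUE)
  expect_error(enhance_color(img, -0.5), "non-negative")
})

test_that("the HSV conversion agrees with the base-R colorspace oracle", {
  set.seed(6)
  n <- 500
  cols <- matrix(sample(0:255, 3 * n, replace = TRUE), nrow = 3)
  px <- array(t(cols), dim = c(n / 2, 2, 3))
  hsv <- blockface:::rgb_to_hsv255(px)
  oracle <- grDevices::rgb2hsv(cols, maxColorValue = 255)
  expect_equal(as.vector(hsv$v) / 255, oracle["v", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.vector(hsv$s), oracle["s", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.vector(hsv$h) / 6, oracle["h", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  back <- blockface:::hsv_to_rgb255(hsv$h, hsv$s, hsv$v)
  expect_equal(array(back, dim = dim(px)), px * 1, tolerance = 1e-9)
})

test_that("brightness transfer matches the reference moments", {
  img <- noisy_image(7, mean = c(100, 90, 80), sd = 20)
  ref <- channel_stats(mean = 120, sd = 10, n = 1000)
  out <- transfer_brightness(img, ref)
  v <- pmax(out$pixels[, , 1], pmax(out$pixels[, , 2], out$pixels[, , 3]))
  clipped <- mean(v == 0 | v == 255)
  expect_lt(clipped, 0.01)
  expect_equal(mean(v), 120, tolerance = 1)
  expect_equal(sd(v), 10, tolerance = 1)
})

test_that("self-referenced brightness transfer is the identity within quantization", {
  img <- noisy_image(8)
  out <- transfer_brightness(img, v_channel_stats(img))
  expect_lte(max(abs(out$pixels - img$pixels)), 1)
  expect_error(transfer_brightness(flat_image(c(50, 50, 50)),
                                   channel_stats(100, 10, 100)), "constant")
})

test_that("exposure-jittered synthetic slices equalize to the reference V mean", {
  acq <- tiny_acq()
  jit <- jitter_spec(rotation_deg = c(0, 0), translation_px = c(0, 0),
                     exposure_gain = c(0.9, 1.1), wb_tint = c(1, 1),
                     d0_mm = Inf)
  stk <- generate_stack(acq, phantom_spec(), n_slices = 5, jitter = jit,
                        seed = 17)
  ref <- v_channel_stats(stk$images[[1]])
  for (i in 2:5) {
    out <- transfer_brightness(stk$images[[i]], ref)
    expect_lt(abs(v_channel_stats(out)$mean - ref$mean), 2)
  }
})
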