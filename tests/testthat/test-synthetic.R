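test_that("identical seeds give bit-identical stacks, different seeds differ", {
  acq <- tiny_acq()
  ph <- phantom_spec()
  s1 <- generate_stack(acq, ph, n_slices = 3, seed = 11)
  s2 <- generate_stack(acq, ph, n_slices = 3, seed = 11)
  s3 <- generate_stack(acq, ph, n_slices = 3, seed = 12)
  for (i in 1:3) {
    expect_identical(s1$images[[i]]$pixels, s2$images[[i]]$pixels)
    expect_identical(s1$truth[[i]]$transform, s2$truth[[i]]$transform)
  }
  expect_false(identical(s1$images[[2]]$pixels, s3$images[[2]]$pixels))
})

test_that("disabled jitter and drift reproduce the same image on every slice", {
  stk <- generate_stack(tiny_acq(), phantom_spec(shape_mod_amp = 0),
                        n_slices = 4, jitter = no_jitter(), seed = 1)
  for (i in 2:4)
    expect_identical(stk$images[[i]]$pixels, stk$images[[1]]$pixels)
})

test_that("ground-truth marker centres equal the analytic transform of the marker positions", {
  acq <- tiny_acq()
  ph <- phantom_spec()
  stk <- generate_stack(acq, ph, n_slices = 5, seed = 7)
  mm <- blockface:::resolve_phantom(ph, acq)$marker_positions_mm
  nominal <- mm / acq$pixel_size_mm - 0.5
  for (rec in stk$truth) {
    tf <- rec$transform
    # independent re-application of the stored transform, written out by hand
    cs <- cos(tf$rotation); sn <- sin(tf$rotation)
    expected <- cbind(
      tf$scale * (cs * nominal[, 1] - sn * nominal[, 2]) + tf$translation[1],
      tf$scale * (sn * nominal[, 1] + cs * nominal[, 2]) + tf$translation[2])
    expect_lt(max(abs(rec$marker_centers_px - expected)), 1e-9)
  }
})

test_that("magnification drift shrinks inter-marker distances monotonically", {
  stk <- generate_stack(tiny_acq(), phantom_spec(), n_slices = 6,
                        jitter = no_jitter(d0_mm = 500), seed = 1)
  mean_dist <- vapply(stk$truth, function(rec) {
    mc <- rec$marker_centers_px
    pr <- utils::combn(4, 2)
    mean(sqrt(rowSums((mc[pr[1, ], ] - mc[pr[2, ], ])^2)))
  }, numeric(1))
  expect_true(all(diff(mean_dist) < 0))
  # drift model: scale_i = d0 / (d0 + i * dz)
  dz <- tiny_acq()$slice_spacing_mm
  expect_equal(vapply(stk$truth, function(r) r$transform$scale, numeric(1)),
               500 / (500 + (0:5) * dz), tolerance = 1e-12)
})

test_that("rendered markers are dark and rendering responds linearly to gain", {
  acq <- tiny_acq()
  ph <- blockface:::resolve_phantom(phantom_spec(), acq)
  id <- similarity_transform()
  mk <- blockface:::nominal_marker_px(ph, acq)
  rec1 <- ground_truth_record(0, id, 1, c(1, 1, 1), mk)
  img1 <- render_slice(ph, acq, rec1)
  for (k in 1:4) {
    v <- img1$pixels[round(mk[k, 2]) + 1, round(mk[k, 1]) + 1, ]
    expect_true(all(v <= 30))
  }
  # doubling the exposure gain doubles every non-saturated pixel
  rec2 <- ground_truth_record(0, id, 2, c(1, 1, 1), mk)
  img2 <- render_slice(ph, acq, rec2)
  doubled <- img2$pixels == pmin(255L, 2L * img1$pixels)
  expect_gt(mean(doubled), 0.98)  # anti-aliased boundary pixels re-quantize
  # exact on regions away from anti-aliased boundaries
  expect_true(all(doubled[1:40, 201:400, ]))            # paraffin strip
  for (k in 1:4)
    expect_true(all(doubled[round(mk[k, 2]) + 1, round(mk[k, 1]) + 1, ]))
})

test_that("white-balance tint shifts paraffin channel ratios as prescribed", {
  acq <- tiny_acq()
  ph <- blockface:::resolve_phantom(phantom_spec(), acq)
  mk <- blockface:::nominal_marker_px(ph, acq)
  id <- similarity_transform()
  # gain 0.8 keeps the tinted paraffin below saturation
  plain <- render_slice(ph, acq, ground_truth_record(0, id, 0.8,
                                                     c(1, 1, 1), mk))
  tinted <- render_slice(ph, acq, ground_truth_record(0, id, 0.8,
                                                      c(1.1, 1, 0.9), mk))
  rows <- 1:40; cols <- 201:400  # pure paraffin strip above the specimen
  ratio <- function(img) mean(img$pixels[rows, cols, 1]) /
    mean(img$pixels[rows, cols, 3])
  expect_equal(ratio(tinted), ratio(plain) * 1.1 / 0.9, tolerance = 0.01)
})

test_that("markers leaving the frame are rejected with a clear error", {
  acq <- tiny_acq()
  ph <- blockface:::resolve_phantom(phantom_spec(), acq)
  mk <- blockface:::nominal_marker_px(ph, acq)
  big <- similarity_transform(translation = c(300, 0))
  rec <- ground_truth_record(0, big, 1, c(1, 1, 1), st_apply(big, mk))
  expect_error(render_slice(ph, acq, rec),
               class = "blockface_marker_out_of_frame")
  expect_error(generate_stack(acq, phantom_spec(), n_slices = 2,
                              jitter = jitter_spec(translation_px = c(300, 301)),
                              seed = 1),
               class = "blockface_marker_out_of_frame")
  expect_error(generate_stack(acq, phantom_spec(), n_slices = 0, seed = 1))
})

test_that("phantom invariants are enforced", {
  # territory colours must be pairwise distinguishable
  expect_error(phantom_spec(territory_colors = rbind(c(200, 55, 55),
                                                     c(210, 60, 60),
                                                     c(45, 180, 65))),
               "distinguishable")
  # markers must lie outside the specimen
  expect_error(blockface:::resolve_phantom(
    phantom_spec(semiaxes_mm = c(85, 60)), tiny_acq()), "outside")
})

test_that("stacks round-trip through disk with their ground truth", {
  acq <- tiny_acq()
  stk <- generate_stack(acq, phantom_spec(), n_slices = 2, seed = 5)
  dir <- withr::local_tempdir()
  write_stack(stk, dir)
  expect_true(file.exists(file.path(dir, "slice_0000.png")))
  images <- read_stack(dir)
  expect_identical(images[[2]]$pixels, stk$images[[2]]$pixels)
  expect_equal(images[[1]]$pixel_size_mm, acq$pixel_size_mm)
  truth <- read_ground_truth(dir)
  expect_equal(truth[[2]]$transform$scale, stk$truth[[2]]$transform$scale)
  expect_equal(truth[[2]]$marker_centers_px, stk$truth[[2]]$marker_centers_px)
})
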