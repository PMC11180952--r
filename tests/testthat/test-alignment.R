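make_fids <- function(centers, slice_index = 0L, dims = c(6000, 4000)) {
  fiducial_set(slice_index,
               data.frame(corner = c("TL", "TR", "BL", "BR"),
                          x = centers[, 1], y = centers[, 2],
                          radius = 10, score = 1),
               dims)
}
ref_centers <- rbind(c(500, 400), c(5500, 420), c(480, 3600), c(5520, 3620))

test_that("magnification factor is the mean inter-marker distance ratio", {
  ref <- make_fids(ref_centers)
  expect_identical(compute_magnification(ref, ref), 1)
  # shrink about the image centre by 0.5 -> factor 2
  ctr <- c(5999 / 2, 3999 / 2)
  shrunk <- make_fids(sweep(0.5 * sweep(ref_centers, 2, ctr), 2, ctr, "+"))
  expect_equal(compute_magnification(shrunk, ref), 2, tolerance = 1e-9)
  # degenerate: two markers closer than 1 px (bypasses set validation,
  # which would already reject such a configuration)
  degen <- make_fids(ref_centers)
  degen$x[2] <- degen$x[1] + 0.5; degen$y[2] <- degen$y[1]
  expect_error(compute_magnification(degen, ref),
               class = "blockface_degenerate_geometry")
})

test_that("rigid fit recovers exact synthetic motions", {
  ref <- make_fids(ref_centers)
  tf <- estimate_rigid(ref, ref, scale = 1)
  expect_equal(tf$scale, 1)
  expect_equal(tf$rotation, 0, tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0), tolerance = 1e-9)
  expect_equal(attr(tf, "rms_residual"), 0, tolerance = 1e-9)

  # src = ref rotated by +5 deg about the image centre; the registering
  # rotation is -5 deg
  th <- 5 * pi / 180
  ctr <- c(5999 / 2, 3999 / 2)
  rot <- function(p, th, ctr) {
    pc <- sweep(p, 2, ctr)
    sweep(cbind(cos(th) * pc[, 1] - sin(th) * pc[, 2],
                sin(th) * pc[, 1] + cos(th) * pc[, 2]), 2, ctr, "+")
  }
  src <- make_fids(rot(ref_centers, th, ctr))
  tf <- estimate_rigid(src, ref, scale = 1)
  expect_equal(tf$rotation, -th, tolerance = 1e-9)
  expect_lt(attr(tf, "rms_residual"), 1e-6)
})

test_that("rigid fit matches a brute-force rotation grid search", {
  set.seed(9)
  for (rep in 1:5) {
    s <- runif(1, 0.8, 1.2)
    th <- runif(1, -0.3, 0.3)
    tr <- runif(2, -40, 40)
    true_tf <- similarity_transform(s, th, tr)
    src_pts <- ref_centers
    ref_pts <- st_apply(true_tf, src_pts)
    est <- blockface:::fit_rigid_points(src_pts, ref_pts, s)

    # oracle: evaluate the SSE on a dense rotation grid, solving for the
    # translation analytically at each grid angle
    grid <- seq(est$rotation - 0.2, est$rotation + 0.2, by = 1e-4)
    pc <- colMeans(src_pts); qc <- colMeans(ref_pts)
    sse <- vapply(grid, function(a) {
      rp <- cbind(cos(a) * src_pts[, 1] - sin(a) * src_pts[, 2],
                  sin(a) * src_pts[, 1] + cos(a) * src_pts[, 2]) * s
      tt <- qc - (s * c(cos(a) * pc[1] - sin(a) * pc[2],
                        sin(a) * pc[1] + cos(a) * pc[2]))
      sum((sweep(rp, 2, tt, "+") - ref_pts)^2)
    }, numeric(1))
    best <- grid[which.min(sse)]
    expect_lt(abs(est$rotation - best), 1e-4)
    expect_equal(est$rotation, th, tolerance = 1e-9)
    expect_equal(est$translation, tr, tolerance = 1e-6)
  }
})

test_that("the attached RMS residual matches an independent recomputation", {
  set.seed(21)
  src_pts <- ref_centers + matrix(rnorm(8, sd = 2), ncol = 2)
  src <- make_fids(src_pts); ref <- make_fids(ref_centers)
  s <- compute_magnification(src, ref)
  tf <- estimate_rigid(src, ref, scale = s)
  expect_identical(tf$scale, s)  # scale estimated once, never re-fit
  mapped <- st_apply(tf, src_pts)
  rms <- sqrt(mean(rowSums((mapped - ref_centers)^2)))
  expect_equal(attr(tf, "rms_residual"), rms, tolerance = 1e-9)
})

test_that("collinear marker geometry is rejected", {
  line <- cbind(c(100, 200, 300, 400), c(100, 200, 300, 400))
  ref <- make_fids(ref_centers)
  expect_error(
    blockface:::fit_rigid_points(line, fiducial_centers(ref), 1),
    class = "blockface_degenerate_geometry")
})

test_that("joint similarity fit agrees with the two-stage fit on clean points", {
  true_tf <- similarity_transform(0.95, 0.02, c(12, -7))
  src <- make_fids(ref_centers)
  ref <- make_fids(st_apply(true_tf, ref_centers))
  joint <- estimate_similarity(src, ref)
  expect_equal(joint$scale, 0.95, tolerance = 1e-9)
  expect_equal(joint$rotation, 0.02, tolerance = 1e-9)
  expect_equal(joint$translation, c(12, -7), tolerance = 1e-6)
})

test_that("resampling under the identity reproduces the image exactly", {
  img <- disk_image(120, 90, c(40.2, 30.7), radius = 9)
  out <- apply_transform(img, similarity_transform())
  expect_identical(out$pixels, img$pixels)
})

test_that("integer translations resample exactly", {
  img <- disk_image(120, 90, c(60.5, 45.5), radius = 9)
  dx <- 7L; dy <- -5L
  out <- apply_transform(img, similarity_transform(translation = c(dx, dy)))
  # output[y, x] == input[y - dy, x - dx] wherever the source is in range
  xs <- (max(0, dx)):(119 + min(0, dx)); ys <- (max(0, dy)):(89 + min(0, dy))
  expect_identical(out$pixels[ys + 1, xs + 1, ],
                   img$pixels[ys - dy + 1, xs - dx + 1, ])
})

test_that("aligning a jittered synthetic stack recovers the ground truth", {
  acq <- tiny_acq()
  stk <- generate_stack(acq, phantom_spec(), n_slices = 4, seed = 13)
  al <- align_stack(stk$images, radius_range = tiny_radius_range())
  for (i in 2:4) {
    expected <- st_invert(stk$truth[[i]]$transform)
    got <- al$transforms[[i]]
    expect_lt(abs(got$scale - expected$scale), 1e-3)
    expect_lt(abs(got$rotation - expected$rotation), 0.1 * pi / 180)
    expect_lt(max(abs(got$translation - expected$translation)), 0.5)
    expect_lt(al$qc$rms_residual_px[i], 0.5)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  transforms_to_csv(al$qc, path)
  expect_equal(read.csv(path)$slice_index, 0:3)
})
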