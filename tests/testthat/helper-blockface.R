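# Shared fixtures and independent oracles for the test suite.

# Small acquisition geometry so unit tests run in well under a second per
# slice: same 150 x 100 mm field at 600 x 400 px (0.25 mm pixels), 50 um
# cuts photographed every tenth cut (0.5 mm spacing = 0.5 mm target voxel).
tiny_acq <- function(...) {
  acquisition_params(resolution_px = c(600, 400), cut_thickness_um = 50,
                     photo_every_k = 10L, target_voxel_mm = 0.5, ...)
}

tiny_radius_range <- function(acq = tiny_acq(), phantom = phantom_spec()) {
  nominal <- phantom$marker_radius_mm / acq$pixel_size_mm
  c(0.7, 1.3) * nominal
}

# Paraffin patch for the tiny geometry, in the aligned downsampled
# (300 x 200 px at 0.5 mm) frame: top strip, clear of markers and specimen.
tiny_patch_cfg <- function() list(x = 140L, y = 2L, w = 25L, h = 20L)

# Independent disk rasterizer for detector tests: anti-aliased by 4 x 4
# supersampling, written directly from the disk equation (never calls the
# package's renderer).
disk_image <- function(w, h, centers, radius, bg = 235, fg = 15,
                       supersample = 4L, pixel_size_mm = 0.1) {
  centers <- rbind(centers)
  off <- ((seq_len(supersample) - 0.5) / supersample) - 0.5
  cov <- matrix(0, h, w)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  for (oy in off) for (ox in off) {
    inside <- rep(FALSE, w * h)
    for (k in seq_len(nrow(centers))) {
      inside <- inside | ((xs + ox - centers[k, 1])^2 +
                            (ys + oy - centers[k, 2])^2 <= radius^2)
    }
    cov <- cov + matrix(inside, h, w)
  }
  cov <- cov / supersample^2
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- bg + (fg - bg) * cov
  raster_image(px, pixel_size_mm)
}

# Brute-force template-matching oracle for a single dark disk: exhaustive
# search over integer centres and radii, scoring mean darkness inside the
# disk minus mean darkness in a surrounding annulus.
template_match_disk <- function(image, cx_range, cy_range, r_range) {
  gray <- 0.299 * image$pixels[, , 1] + 0.587 * image$pixels[, , 2] +
    0.114 * image$pixels[, , 3]
  inv <- 255 - gray
  h <- nrow(inv); w <- ncol(inv)
  best <- list(score = -Inf)
  for (r in r_range[1]:r_range[2]) {
    for (cy in cy_range[1]:cy_range[2]) {
      for (cx in cx_range[1]:cx_range[2]) {
        xs <- max(0, cx - r - 3):min(w - 1, cx + r + 3)
        ys <- max(0, cy - r - 3):min(h - 1, cy + r + 3)
        win <- inv[ys + 1, xs + 1, drop = FALSE]
        d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
        ins <- d2 <= r^2
        ann <- d2 > r^2 & d2 <= (r + 3)^2
        score <- mean(win[ins]) - mean(win[ann])
        if (score > best$score)
          best <- list(score = score, x = cx, y = cy, r = r)
      }
    }
  }
  best
}

# Shared default-scale reconstruction used by the acceptance checks: one
# n = 10 stack at the default 1500 x 1000 px geometry, pushed through the
# full pipeline once and cached for the session.
default_reconstruction <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- pipeline_config(seed = 1L)
    stack_dir <- file.path(tempdir(), "bf-acceptance-stack")
    simulate_to_dir(cfg, stack_dir, n_slices = 10, seed = 1L)
    nii <- file.path(tempdir(), "bf-acceptance-vol.nii.gz")
    res <- run_pipeline(stack_dir, nii, cfg, verbose = FALSE)
    cache <<- list(config = cfg, stack_dir = stack_dir, nii = nii,
                   result = res)
    cache
  }
})
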