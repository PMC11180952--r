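#' Phantom specimen description for the synthetic blockface generator
#'
#' Describes a digital phantom emulating a paraffin block containing a
#' specimen whose sub-regions were labeled with three distinctly colored
#' injection media (blue/red/green, as used to mark the anterior, middle and
#' posterior cerebral artery territories), plus four dark circular fiducial
#' markers drilled near the block corners and filled with black paraffin.
#'
#' The specimen cross-section is an ellipse whose semi-axes are modulated
#' slowly along the stack (so consecutive blockfaces differ, as real anatomy
#' does), split into three angular sectors, one per colored territory.
#'
#' @param center_mm Specimen centre `(x, y)` in mm, or `NULL` for the centre
#'   of the field of view.
#' @param semiaxes_mm Ellipse semi-axes `(a, b)` in mm.
#' @param shape_mod_amp,shape_mod_period Relative amplitude and period (in
#'   slices) of the sinusoidal per-slice modulation of the semi-axes.
#' @param territory_colors 3 x 3 matrix of RGB rows for the three territories.
#'   Rows must be pairwise distinguishable: maximum absolute channel
#'   difference at least 64.
#' @param sector_angles_deg Length-3 increasing vector of sector start angles
#'   (degrees) splitting the ellipse into the three territories.
#' @param marker_positions_mm 4 x 2 matrix of marker centres in mm (order
#'   TL, TR, BL, BR), or `NULL` for corners inset by `marker_inset_mm`.
#' @param marker_inset_mm Corner inset used when `marker_positions_mm` is
#'   `NULL`.
#' @param marker_radius_mm Radius of the drilled fiducial markers in mm.
#' @param marker_rgb RGB of the black-paraffin markers (dark).
#' @param background_rgb RGB of the surrounding paraffin.
#' @return An object of class `blockface_phantom`.
#' @export
phantom_spec <- function(center_mm = NULL,
                         semiaxes_mm = c(55, 35),
                         shape_mod_amp = 0.05,
                         shape_mod_period = 8,
                         territory_colors = rbind(c(60, 70, 200),
                                                  c(200, 55, 55),
                                                  c(45, 180, 65)),
                         sector_angles_deg = c(-90, 30, 150),
                         marker_positions_mm = NULL,
                         marker_inset_mm = 10,
                         marker_radius_mm = 2.5,
                         marker_rgb = c(15, 15, 15),
                         background_rgb = c(235, 232, 222)) {
  territory_colors <- rbind(territory_colors)
  stopifnot(nrow(territory_colors) == 3L, ncol(territory_colors) == 3L,
            length(semiaxes_mm) == 2L, all(semiaxes_mm > 0),
            shape_mod_amp >= 0, shape_mod_amp < 1, shape_mod_period > 0,
            length(sector_angles_deg) == 3L,
            !is.unsorted(sector_angles_deg, strictly = TRUE),
            marker_radius_mm > 0, marker_inset_mm > 0,
            length(marker_rgb) == 3L, length(background_rgb) == 3L)
  for (i in 1:2) for (j in (i + 1):3) {
    if (max(abs(territory_colors[i, ] - territory_colors[j, ])) < 64)
      stop(sprintf(paste0("territory colors %d and %d are not distinguishable",
                          " (max channel difference < 64)"), i, j))
  }
  if (!is.null(marker_positions_mm)) {
    marker_positions_mm <- rbind(marker_positions_mm)
    stopifnot(nrow(marker_positions_mm) == 4L, ncol(marker_positions_mm) == 2L)
  }
  structure(list(
    center_mm = center_mm, semiaxes_mm = as.numeric(semiaxes_mm),
    shape_mod_amp = shape_mod_amp, shape_mod_period = shape_mod_period,
    territory_colors = territory_colors,
    sector_angles_deg = as.numeric(sector_angles_deg),
    marker_positions_mm = marker_positions_mm,
    marker_inset_mm = marker_inset_mm,
    marker_radius_mm = marker_radius_mm,
    marker_rgb = as.numeric(marker_rgb),
    background_rgb = as.numeric(background_rgb)
  ), class = "blockface_phantom")
}

# Fill in FOV-dependent defaults and check markers lie outside the specimen.
resolve_phantom <- function(phantom, params) {
  stopifnot(inherits(phantom, "blockface_phantom"),
            inherits(params, "blockface_acquisition"))
  if (is.null(phantom$center_mm))
    phantom$center_mm <- params$fov_mm / 2
  if (is.null(phantom$marker_positions_mm)) {
    d <- phantom$marker_inset_mm
    w <- params$fov_mm[1]; h <- params$fov_mm[2]
    phantom$marker_positions_mm <- rbind(
      TL = c(d, d), TR = c(w - d, d), BL = c(d, h - d), BR = c(w - d, h - d))
  } else if (is.null(rownames(phantom$marker_positions_mm))) {
    rownames(phantom$marker_positions_mm) <- c("TL", "TR", "BL", "BR")
  }
  # markers must sit outside the specimen even at maximum shape modulation
  amax <- phantom$semiaxes_mm * (1 + phantom$shape_mod_amp)
  dxy <- sweep(phantom$marker_positions_mm, 2, phantom$center_mm)
  rn <- sqrt((dxy[, 1] / amax[1])^2 + (dxy[, 2] / amax[2])^2)
  margin <- phantom$marker_radius_mm / min(amax)
  if (any(rn <= 1 + margin))
    stop("phantom markers must lie outside the specimen ellipse; marker(s) ",
         paste(which(rn <= 1 + margin), collapse = ", "), " overlap it")
  phantom
}

#' Per-slice jitter and drift model of the synthetic acquisition
#'
#' The camera is nominally fixed, but three disturbance sources are
#' emulated, each drawn per photograph from a uniform range:
#' small in-plane rotation and translation (vibration of the rig during
#' cutting), a per-image exposure gain and per-channel white-balance tint
#' (lighting/reflection variability), and a deterministic magnification
#' drift: the camera-to-blockface distance grows by one slice spacing per
#' photograph, so slice i is scaled by `d0 / (d0 + i * dz)` (pinhole model
#' with initial distance `d0`). `d0_mm = Inf` disables the drift.
#'
#' @param rotation_deg,translation_px,exposure_gain,wb_tint Length-2
#'   `c(min, max)` uniform ranges. The white-balance tint is drawn
#'   independently per channel.
#' @param d0_mm Initial camera-to-blockface distance in mm.
#' @return An object of class `blockface_jitter`.
#' @export
jitter_spec <- function(rotation_deg = c(-1, 1),
                        translation_px = c(-20, 20),
                        exposure_gain = c(0.9, 1.1),
                        wb_tint = c(0.95, 1.05),
                        d0_mm = 500) {
  rng <- list(rotation_deg = rotation_deg, translation_px = translation_px,
              exposure_gain = exposure_gain, wb_tint = wb_tint)
  for (nm in names(rng)) {
    v <- rng[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      stop("`", nm, "` must be a finite c(min, max) range")
  }
  stopifnot(exposure_gain[1] > 0, wb_tint[1] > 0, d0_mm > 0)
  structure(c(rng, list(d0_mm = d0_mm)), class = "blockface_jitter")
}

#' @rdname jitter_spec
#' @export
no_jitter <- function(d0_mm = Inf) {
  jitter_spec(rotation_deg = c(0, 0), translation_px = c(0, 0),
              exposure_gain = c(1, 1), wb_tint = c(1, 1), d0_mm = d0_mm)
}

#' Ground-truth record for one synthetic blockface
#'
#' @param slice_index 0-based slice index.
#' @param transform [similarity_transform()] mapping nominal phantom pixel
#'   coordinates into this image's pixel coordinates.
#' @param exposure_gain Positive scalar exposure multiplier.
#' @param wb_tint Positive length-3 per-channel gain.
#' @param marker_centers_px 4 x 2 matrix (rows TL, TR, BL, BR) of the true
#'   marker centres in image px: the transform image of the physical marker
#'   positions.
#' @return An object of class `blockface_truth`.
#' @export
ground_truth_record <- function(slice_index, transform, exposure_gain,
                                wb_tint, marker_centers_px) {
  stopifnot(inherits(transform, "blockface_transform"),
            exposure_gain > 0, length(wb_tint) == 3L, all(wb_tint > 0))
  marker_centers_px <- rbind(marker_centers_px)
  stopifnot(nrow(marker_centers_px) == 4L, ncol(marker_centers_px) == 2L)
  if (is.null(rownames(marker_centers_px)))
    rownames(marker_centers_px) <- c("TL", "TR", "BL", "BR")
  structure(list(slice_index = as.integer(slice_index), transform = transform,
                 exposure_gain = as.numeric(exposure_gain),
                 wb_tint = as.numeric(wb_tint),
                 marker_centers_px = marker_centers_px),
            class = "blockface_truth")
}

# Territory/marker label of physical points (x, y) in mm for slice i.
# 0 = paraffin, 1..3 = territories, 4 = marker.
label_at_points <- function(phantom, slice_index, x_mm, y_mm) {
  m <- 1 + phantom$shape_mod_amp *
    sin(2 * pi * slice_index / phantom$shape_mod_period)
  a <- phantom$semiaxes_mm[1] * m
  b <- phantom$semiaxes_mm[2] * m
  dx <- (x_mm - phantom$center_mm[1]) / a
  dy <- (y_mm - phantom$center_mm[2]) / b
  lab <- integer(length(dx))
  inside <- dx * dx + dy * dy <= 1
  if (any(inside)) {
    ang <- atan2(dy[inside], dx[inside]) * 180 / pi
    rel <- (ang - phantom$sector_angles_deg[1]) %% 360
    bounds <- c(0, (phantom$sector_angles_deg[2:3] -
                      phantom$sector_angles_deg[1]) %% 360)
    lab[inside] <- findInterval(rel, bounds)
  }
  mp <- phantom$marker_positions_mm
  r2 <- phantom$marker_radius_mm^2
  for (k in 1:4) {
    hit <- (x_mm - mp[k, 1])^2 + (y_mm - mp[k, 2])^2 <= r2
    lab[hit] <- 4L
  }
  lab
}

# 5 x 3 palette indexed by label + 1: paraffin, 3 territories, marker.
phantom_palette <- function(phantom) {
  rbind(phantom$background_rgb, phantom$territory_colors, phantom$marker_rgb)
}

#' Rasterize one synthetic blockface photograph
#'
#' Renders the phantom under the ground-truth transform, exposure gain and
#' white-balance tint of `truth`. Rasterization is anti-aliased: pixels near
#' a region boundary are supersampled on a 4 x 4 subgrid and box-averaged,
#' which makes subpixel marker-centre recovery meaningful. The result is
#' quantized to 8 bits (round-half-up, clipped at 255). Marker interiors are
#' darker than every other pixel, guaranteeing Hough-detectable contrast.
#'
#' @param phantom A [phantom_spec()].
#' @param params An [acquisition_params()].
#' @param truth A [ground_truth_record()]; its transform must keep all four
#'   markers (including their radius) inside the frame.
#' @return A [raster_image()].
#' @export
render_slice <- function(phantom, params, truth) {
  phantom <- resolve_phantom(phantom, params)
  stopifnot(inherits(truth, "blockface_truth"))
  w <- params$resolution_px[1]; h <- params$resolution_px[2]
  ps <- params$pixel_size_mm
  check_markers_in_frame(phantom, params, truth)

  inv <- st_invert(truth$transform)
  # labels at pixel centres
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  p <- st_apply(inv, cbind(gx, gy))
  lab <- label_at_points(phantom, truth$slice_index,
                         (p[, 1] + 0.5) * ps, (p[, 2] + 0.5) * ps)
  labm <- matrix(lab, nrow = h, ncol = w)

  # boundary band: pixels whose 4-neighbourhood labels disagree, dilated by 1
  diffm <- neighbor_disagreement(labm)
  band <- neighbor_or(diffm)
  bi <- which(band)  # column-major indices into h x w

  pal <- phantom_palette(phantom)
  pix <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) pix[, , ch] <- matrix(pal[lab + 1L, ch], h, w)

  if (length(bi)) {
    # 4 x 4 supersampling of boundary pixels
    by <- (bi - 1L) %% h          # 0-based row (y)
    bx <- (bi - 1L) %/% h         # 0-based col (x)
    off <- (0:3 + 0.5) / 4 - 0.5
    acc <- matrix(0, nrow = length(bi), ncol = 3)
    for (oy in off) for (ox in off) {
      q <- st_apply(inv, cbind(bx + ox, by + oy))
      l <- label_at_points(phantom, truth$slice_index,
                           (q[, 1] + 0.5) * ps, (q[, 2] + 0.5) * ps)
      acc <- acc + pal[l + 1L, , drop = FALSE]
    }
    acc <- acc / 16
    for (ch in 1:3) {
      m <- pix[, , ch]; m[bi] <- acc[, ch]; pix[, , ch] <- m
    }
  }

  g <- truth$exposure_gain * truth$wb_tint
  for (ch in 1:3) pix[, , ch] <- pix[, , ch] * g[ch]
  raster_image(pix, ps)
}

neighbor_disagreement <- function(labm) {
  h <- nrow(labm); w <- ncol(labm)
  d <- matrix(FALSE, h, w)
  d[-h, ] <- d[-h, ] | labm[-h, ] != labm[-1, ]
  d[-1, ] <- d[-1, ] | labm[-1, ] != labm[-h, ]
  d[, -w] <- d[, -w] | labm[, -w] != labm[, -1]
  d[, -1] <- d[, -1] | labm[, -1] != labm[, -w]
  d
}

neighbor_or <- function(m) {
  h <- nrow(m); w <- ncol(m)
  o <- m
  o[-h, ] <- o[-h, ] | m[-1, ]
  o[-1, ] <- o[-1, ] | m[-h, ]
  o[, -w] <- o[, -w] | m[, -1]
  o[, -1] <- o[, -1] | m[, -w]
  o
}

check_markers_in_frame <- function(phantom, params, truth) {
  r_px <- phantom$marker_radius_mm / params$pixel_size_mm
  w <- params$resolution_px[1]; h <- params$resolution_px[2]
  mc <- truth$marker_centers_px
  out <- mc[, 1] < r_px | mc[, 1] > (w - 1) - r_px |
         mc[, 2] < r_px | mc[, 2] > (h - 1) - r_px
  if (any(out))
    bf_stop(sprintf(
      "slice %d: marker(s) %s outside the frame; reduce jitter ranges",
      truth$slice_index, paste(rownames(mc)[out], collapse = ", ")),
      "blockface_marker_out_of_frame")
  invisible(TRUE)
}

# nominal (untransformed) marker centres in px
nominal_marker_px <- function(phantom, params) {
  phantom$marker_positions_mm / params$pixel_size_mm - 0.5
}

#' Generate a synthetic blockface stack with ground truth
#'
#' Emulates a full serial-sectioning photography session: `n_slices`
#' photographs of the phantom, each with a deterministic magnification drift
#' (camera distance grows by one slice spacing per photograph) and random
#' rotation/translation jitter, exposure gain and white-balance tint drawn
#' from `jitter`. Slice 0 is the nominal reference: unit scale, no jitter,
#' neutral exposure — its pixel frame is the frame the pipeline aligns to.
#' The same seed always yields a bit-identical stack.
#'
#' @param params An [acquisition_params()].
#' @param phantom A [phantom_spec()].
#' @param n_slices Number of blockfaces (at least 2).
#' @param jitter A [jitter_spec()].
#' @param seed Integer RNG seed.
#' @return A list with `images` (list of [raster_image()]) and `truth`
#'   (list of [ground_truth_record()]).
#' @examples
#' acq <- acquisition_params(resolution_px = c(300, 200))
#' stk <- generate_stack(acq, phantom_spec(marker_radius_mm = 5),
#'                       n_slices = 2, jitter = no_jitter(), seed = 1)
#' stk$truth[[1]]$marker_centers_px
#' @export
generate_stack <- function(params, phantom, n_slices,
                           jitter = jitter_spec(), seed = 1L) {
  stopifnot(inherits(params, "blockface_acquisition"),
            inherits(jitter, "blockface_jitter"))
  if (!is.numeric(n_slices) || n_slices < 2)
    stop("`n_slices` must be an integer >= 2")
  n_slices <- as.integer(n_slices)
  phantom <- resolve_phantom(phantom, params)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  dz <- params$slice_spacing_mm
  w <- params$resolution_px[1]; h <- params$resolution_px[2]
  cpx <- c((w - 1) / 2, (h - 1) / 2)
  mk_nom <- nominal_marker_px(phantom, params)

  truth <- vector("list", n_slices)
  images <- vector("list", n_slices)
  for (i in seq_len(n_slices) - 1L) {
    s <- if (is.finite(jitter$d0_mm))
      jitter$d0_mm / (jitter$d0_mm + i * dz) else 1
    if (i == 0L) {
      rot <- 0; tr <- c(0, 0); gain <- 1; tint <- c(1, 1, 1)
    } else {
      rot <- stats::runif(1, jitter$rotation_deg[1],
                          jitter$rotation_deg[2]) * pi / 180
      tr <- stats::runif(2, jitter$translation_px[1], jitter$translation_px[2])
      gain <- stats::runif(1, jitter$exposure_gain[1], jitter$exposure_gain[2])
      tint <- stats::runif(3, jitter$wb_tint[1], jitter$wb_tint[2])
    }
    # scale+rotate about the image centre, then translate
    cs <- cos(rot); sn <- sin(rot)
    rc <- c(cs * cpx[1] - sn * cpx[2], sn * cpx[1] + cs * cpx[2])
    tf <- similarity_transform(scale = s, rotation = rot,
                               translation = cpx + tr - s * rc)
    rec <- ground_truth_record(i, tf, gain, tint, st_apply(tf, mk_nom))
    check_markers_in_frame(phantom, params, rec)
    truth[[i + 1L]] <- rec
    images[[i + 1L]] <- render_slice(phantom, params, rec)
  }
  list(images = images, truth = truth)
}

#' Write / read a blockface stack on disk
#'
#' `write_stack` saves the images as zero-padded numbered files
#' (`slice_0000.png`, ...) plus a JSON sidecar `ground_truth.json` holding
#' the pixel size and, when available, every ground-truth record.
#' `read_stack` loads the numbered images back (PNG or JPEG);
#' `read_ground_truth` restores the sidecar records.
#'
#' @param stack A list with `images` (and optionally `truth`), as returned
#'   by [generate_stack()], or a bare list of rasters.
#' @param dir Directory to write into (created if missing).
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @return `write_stack` returns `dir` invisibly; `read_stack` returns a
#'   list of [raster_image()]; `read_ground_truth` a list of
#'   [ground_truth_record()] or `NULL` when no sidecar is present.
#' @export
write_stack <- function(stack, dir, format = c("png", "jpeg")) {
  format <- match.arg(format)
  if (is_raster_image(stack[[1]])) stack <- list(images = stack)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") "png" else "jpg"
  for (i in seq_along(stack$images)) {
    write_raster(stack$images[[i]],
                 file.path(dir, sprintf("slice_%04d.%s", i - 1L, ext)))
  }
  sidecar <- list(pixel_size_mm = stack$images[[1]]$pixel_size_mm)
  if (!is.null(stack$truth)) {
    sidecar$truth <- lapply(stack$truth, function(tr) list(
      slice_index = tr$slice_index,
      scale = tr$transform$scale,
      rotation_rad = tr$transform$rotation,
      translation_px = tr$transform$translation,
      exposure_gain = tr$exposure_gain,
      wb_tint = tr$wb_tint,
      marker_centers_px = tr$marker_centers_px))
  }
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @param pixel_size_mm Pixel size in mm; taken from the sidecar when `NULL`.
#' @export
read_stack <- function(dir, pixel_size_mm = NULL) {
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.(png|jpe?g)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no slice_*.png / slice_*.jpg files found in ", dir)
  if (is.null(pixel_size_mm)) {
    sc <- file.path(dir, "ground_truth.json")
    if (!file.exists(sc))
      stop("`pixel_size_mm` not given and no ground_truth.json sidecar in ",
           dir)
    pixel_size_mm <- jsonlite::read_json(sc)$pixel_size_mm
  }
  lapply(files, read_raster, pixel_size_mm = pixel_size_mm)
}

#' @rdname write_stack
#' @export
read_ground_truth <- function(dir) {
  sc <- file.path(dir, "ground_truth.json")
  if (!file.exists(sc)) return(NULL)
  side <- jsonlite::read_json(sc)
  if (is.null(side$truth)) return(NULL)
  lapply(side$truth, function(tr) {
    mc <- do.call(rbind, lapply(tr$marker_centers_px, unlist))
    rownames(mc) <- c("TL", "TR", "BL", "BR")
    ground_truth_record(
      tr$slice_index,
      similarity_transform(tr$scale, tr$rotation_rad,
                           unlist(tr$translation_px)),
      tr$exposure_gain, unlist(tr$wb_tint), mc)
  })
}

#' Ground-truth label map of the phantom on the volume grid
#'
#' Evaluates the phantom's region label (0 paraffin, 1-3 territories,
#' 4 marker) at every voxel centre of the reconstructed volume's grid, in
#' the reference (slice 0) frame. This is the oracle against which territory
#' classification of a reconstructed synthetic volume is scored.
#'
#' @param phantom A [phantom_spec()].
#' @param params An [acquisition_params()].
#' @param n_slices Number of slices.
#' @param target_mm In-plane voxel size of the volume grid (default: the
#'   acquisition's target voxel size).
#' @return Integer array `D x H x W` of labels.
#' @export
phantom_label_map <- function(phantom, params, n_slices,
                              target_mm = params$target_voxel_mm) {
  phantom <- resolve_phantom(phantom, params)
  ps <- params$pixel_size_mm
  w_out <- round(params$resolution_px[1] * ps / target_mm)
  h_out <- round(params$resolution_px[2] * ps / target_mm)
  x_mm <- ((0:(w_out - 1)) + 0.5) * target_mm
  y_mm <- ((0:(h_out - 1)) + 0.5) * target_mm
  gx <- rep(x_mm, each = h_out)
  gy <- rep(y_mm, times = w_out)
  out <- array(0L, dim = c(n_slices, h_out, w_out))
  for (i in seq_len(n_slices) - 1L) {
    out[i + 1L, , ] <- matrix(label_at_points(phantom, i, gx, gy),
                              h_out, w_out)
  }
  out
}

#' Erode a 3D label map by one voxel
#'
#' Keeps a voxel's label only where all 6-connected neighbours (within the
#' array bounds) carry the same label; boundary-adjacent voxels are set to
#' -1 (excluded). Used to score territory recovery away from region borders.
#'
#' @param labels Integer `D x H x W` array.
#' @return Same-shaped integer array with border voxels set to -1.
#' @export
erode_label_map <- function(labels) {
  d <- dim(labels)
  same <- array(TRUE, dim = d)
  eq <- function(a, b) a == b
  if (d[1] > 1L) {
    s <- eq(labels[-1, , , drop = FALSE], labels[-d[1], , , drop = FALSE])
    same[-1, , ] <- same[-1, , , drop = FALSE] & s
    same[-d[1], , ] <- same[-d[1], , , drop = FALSE] & s
  }
  if (d[2] > 1L) {
    s <- eq(labels[, -1, , drop = FALSE], labels[, -d[2], , drop = FALSE])
    same[, -1, ] <- same[, -1, , drop = FALSE] & s
    same[, -d[2], ] <- same[, -d[2], , drop = FALSE] & s
  }
  if (d[3] > 1L) {
    s <- eq(labels[, , -1, drop = FALSE], labels[, , -d[3], drop = FALSE])
    same[, , -1] <- same[, , -1, drop = FALSE] & s
    same[, , -d[3]] <- same[, , -d[3], drop = FALSE] & s
  }
  out <- labels
  out[!same] <- -1L
  out
}
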