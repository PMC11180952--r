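#' Magnification factor from inter-marker distances
#'
#' As the block is cut down, the camera-to-blockface distance grows and the
#' specimen shrinks on the photographs. Because the fiducial markers are at
#' fixed physical positions, the ratio of inter-marker distances between an
#' image and the reference measures this magnification change directly.
#' Returns the mean over all six corner pairs of
#' `reference distance / source distance`.
#'
#' @param fids_src,fids_ref Complete [fiducial_set()]s (four labeled
#'   markers each) for the source and reference image.
#' @return Dimensionless scale factor to apply to the source image.
#' @export
compute_magnification <- function(fids_src, fids_ref) {
  ps <- fiducial_centers(fids_src)
  qs <- fiducial_centers(fids_ref)
  pairs <- utils::combn(4L, 2L)
  ds <- sqrt(rowSums((ps[pairs[1, ], ] - ps[pairs[2, ], ])^2))
  dr <- sqrt(rowSums((qs[pairs[1, ], ] - qs[pairs[2, ], ])^2))
  if (any(ds < 1))
    bf_stop("degenerate marker geometry: a source inter-marker distance is below 1 px",
            "blockface_degenerate_geometry")
  mean(dr / ds)
}

#' Least-squares rigid registration of labeled fiducials
#'
#' Estimates the rotation and translation registering the scale-corrected
#' source markers onto the reference markers, in closed form (2D
#' orthogonal-Procrustes / Kabsch with the scale fixed a priori): the
#' rotation angle is `atan2` of the cross- and dot-products of the centred
#' point sets and the translation aligns the centroids. The given `scale`
#' (from [compute_magnification()]) is folded into the returned transform
#' unchanged, honouring the two-stage structure of the method: magnification
#' first, then rigid motion. The RMS corner-to-corner residual of the fit is
#' attached to the result as attribute `"rms_residual"`.
#'
#' @inheritParams compute_magnification
#' @param scale Scale factor estimated separately; default 1.
#' @return A [similarity_transform()] mapping source to reference
#'   coordinates, with attribute `rms_residual` (px).
#' @export
estimate_rigid <- function(fids_src, fids_ref, scale = 1) {
  p <- fiducial_centers(fids_src)
  q <- fiducial_centers(fids_ref)
  stopifnot(identical(rownames(p), rownames(q)), scale > 0)
  fit_rigid_points(p, q, scale)
}

fit_rigid_points <- function(p, q, scale) {
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  sv <- svd(pp)$d
  if (sv[1] < 1e-9 || sv[2] / sv[1] < 1e-9)
    bf_stop("degenerate marker geometry: centred source points are collinear or coincident",
            "blockface_degenerate_geometry")
  cross <- sum(pp[, 1] * qq[, 2] - pp[, 2] * qq[, 1])
  dot <- sum(pp[, 1] * qq[, 1] + pp[, 2] * qq[, 2])
  theta <- atan2(cross, dot)
  cs <- cos(theta); sn <- sin(theta)
  rp <- c(cs * pc[1] - sn * pc[2], sn * pc[1] + cs * pc[2])
  tf <- similarity_transform(scale = scale, rotation = theta,
                             translation = qc - scale * rp)
  res <- st_apply(tf, p) - q
  attr(tf, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Joint four-parameter similarity fit (optional mode)
#'
#' Full least-squares similarity (scale, rotation, translation) on the
#' labeled marker correspondences in one step, for comparison with the
#' two-stage magnification-then-rigid estimate of [estimate_rigid()].
#'
#' @inheritParams compute_magnification
#' @return A [similarity_transform()] with attribute `rms_residual`.
#' @export
estimate_similarity <- function(fids_src, fids_ref) {
  p <- fiducial_centers(fids_src)
  q <- fiducial_centers(fids_ref)
  stopifnot(identical(rownames(p), rownames(q)))
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  sv <- svd(pp)$d
  if (sv[1] < 1e-9 || sv[2] / sv[1] < 1e-9)
    bf_stop("degenerate marker geometry: centred source points are collinear or coincident",
            "blockface_degenerate_geometry")
  cross <- sum(pp[, 1] * qq[, 2] - pp[, 2] * qq[, 1])
  dot <- sum(pp[, 1] * qq[, 1] + pp[, 2] * qq[, 2])
  theta <- atan2(cross, dot)
  s <- sqrt(cross^2 + dot^2) / sum(pp^2)
  cs <- cos(theta); sn <- sin(theta)
  rp <- c(cs * pc[1] - sn * pc[2], sn * pc[1] + cs * pc[2])
  tf <- similarity_transform(scale = s, rotation = theta,
                             translation = qc - s * rp)
  res <- st_apply(tf, p) - q
  attr(tf, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Resample an image under a similarity transform
#'
#' Produces the image as seen in the reference frame: each output pixel `q`
#' is sampled from the source image at `T^{-1}(q)` by bicubic interpolation
#' (Keys kernel, a = -0.5). Output pixels whose source location falls
#' outside the image are filled with `fill` (default: the per-channel
#' median of a 10 px border ring of the source image, which on blockface
#' photographs is paraffin). Channels are clipped to `[0, 255]` and
#' re-quantized.
#'
#' @param image Source [raster_image()].
#' @param t [similarity_transform()] mapping source to reference
#'   coordinates.
#' @param out_dims Length-2 `(width, height)` of the output (default: the
#'   source dims).
#' @param fill Length-3 RGB fill colour, or `NULL` for the border median.
#' @return A [raster_image()] in the reference frame.
#' @export
apply_transform <- function(image, t, out_dims = NULL, fill = NULL) {
  stopifnot(is_raster_image(image), inherits(t, "blockface_transform"))
  d <- dim(image$pixels)
  h <- d[1]; w <- d[2]
  if (is.null(out_dims)) out_dims <- c(w, h)
  if (is.null(fill)) fill <- border_median_color(image)
  wo <- as.integer(out_dims[1]); ho <- as.integer(out_dims[2])

  inv <- st_invert(t)
  qx <- rep(0:(wo - 1), each = ho)
  qy <- rep(0:(ho - 1), times = wo)
  p <- st_apply(inv, cbind(qx, qy))
  px <- p[, 1]; py <- p[, 2]
  inb <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1

  x0 <- floor(px); fx <- px - x0
  y0 <- floor(py); fy <- py - y0
  wx <- cubic_weights(fx)
  wy <- cubic_weights(fy)
  cols <- lapply(-1:2, function(i) pmin(pmax(x0 + i, 0), w - 1))
  rows <- lapply(-1:2, function(j) pmin(pmax(y0 + j, 0), h - 1))

  out <- array(0, dim = c(ho, wo, 3))
  for (ch in 1:3) {
    src <- image$pixels[, , ch]
    accy <- 0
    for (j in 1:4) {
      accx <- 0
      for (i in 1:4) {
        idx <- rows[[j]] + cols[[i]] * h + 1
        accx <- accx + wx[[i]] * src[idx]
      }
      accy <- accy + wy[[j]] * accx
    }
    accy[!inb] <- fill[ch]
    out[, , ch] <- matrix(accy, ho, wo)
  }
  raster_image(out, image$pixel_size_mm)
}

# Keys bicubic convolution weights (a = -0.5) for offsets -1, 0, 1, 2.
cubic_weights <- function(f) {
  a <- -0.5
  k <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  lapply(-1:2, function(m) k(f - m))
}

#' Align a blockface stack onto its first image
#'
#' Runs the coregistration stage of the pipeline: for every image, the
#' scale factor is estimated from inter-marker distances against the
#' reference ([compute_magnification()]), the rigid motion is fitted on the
#' scale-corrected marker correspondences ([estimate_rigid()]), and the
#' image is resampled into the reference frame ([apply_transform()]) with
#' out-of-frame pixels filled with the reference's paraffin border median.
#'
#' @param images List of [raster_image()]s, first image = registration
#'   target.
#' @param fiducials Optional list of [fiducial_set()]s (detected if
#'   `NULL`).
#' @param radius_range Radius search range in px for marker detection
#'   (needed when `fiducials` is `NULL`).
#' @param joint If `TRUE`, use the one-step similarity fit
#'   ([estimate_similarity()]) instead of the two-stage
#'   magnification-then-rigid estimate.
#' @param ... Passed to [detect_fiducials()].
#' @return A list with `aligned` (list of rasters), `transforms` (list of
#'   [similarity_transform()]s, identity for the reference) and `qc`, a
#'   data frame with per-slice scale, rotation (deg), translation and RMS
#'   marker residual (px).
#' @export
align_stack <- function(images, fiducials = NULL, radius_range = NULL,
                        joint = FALSE, ...) {
  stopifnot(length(images) >= 2L)
  if (is.null(fiducials)) {
    if (is.null(radius_range))
      stop("`radius_range` is required when `fiducials` is NULL")
    fiducials <- lapply(seq_along(images), function(i)
      detect_fiducials(images[[i]], radius_range, slice_index = i - 1L, ...))
  }
  ref <- fiducials[[1]]
  dref <- dim(images[[1]]$pixels)
  fill <- border_median_color(images[[1]])
  n <- length(images)
  transforms <- vector("list", n)
  aligned <- vector("list", n)
  qc <- data.frame(slice_index = seq_len(n) - 1L, scale = NA_real_,
                   rotation_deg = NA_real_, tx = NA_real_, ty = NA_real_,
                   rms_residual_px = NA_real_)
  for (i in seq_len(n)) {
    if (i == 1L) {
      tf <- similarity_transform()
      attr(tf, "rms_residual") <- 0
      aligned[[i]] <- images[[i]]
    } else {
      tf <- if (joint) {
        estimate_similarity(fiducials[[i]], ref)
      } else {
        s <- compute_magnification(fiducials[[i]], ref)
        estimate_rigid(fiducials[[i]], ref, scale = s)
      }
      aligned[[i]] <- apply_transform(images[[i]], tf,
                                      out_dims = c(dref[2], dref[1]),
                                      fill = fill)
    }
    transforms[[i]] <- tf
    qc$scale[i] <- tf$scale
    qc$rotation_deg[i] <- tf$rotation * 180 / pi
    qc$tx[i] <- tf$translation[1]
    qc$ty[i] <- tf$translation[2]
    qc$rms_residual_px[i] <- attr(tf, "rms_residual")
  }
  list(aligned = aligned, transforms = transforms, qc = qc)
}

#' Export per-slice transforms and residuals as CSV
#'
#' @param qc The `qc` data frame returned by [align_stack()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
transforms_to_csv <- function(qc, path) {
  utils::write.csv(qc, path, row.names = FALSE)
  invisible(path)
}
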