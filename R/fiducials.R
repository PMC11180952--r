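#' Detect dark circular fiducial markers with a circular Hough transform
#'
#' Finds the strongest dark-circle hypotheses in a blockface photograph.
#' The detector follows the classical gradient-direction formulation:
#' the image is converted to luma and inverted (markers are dark), a Sobel
#' gradient map is computed, and every strong edge pixel casts a vote one
#' radius along its gradient direction (which points towards the centre of a
#' dark disk) for each candidate radius. Accumulator peaks are extracted
#' with non-maximum suppression (candidate centres must be at least
#' `2 * max(radius_range)` apart) and each surviving centre is refined to
#' subpixel precision as the darkness-weighted centroid of below-threshold
#' pixels inside the detected circle, with the threshold chosen by Otsu's
#' method over the circle's interior and a surrounding annulus.
#'
#' @param image A [raster_image()].
#' @param radius_range Length-2 `c(min, max)` radius search range in px;
#'   must lie within `(0, min(image dims) / 4)`.
#' @param n_expected Number of markers to return (default 4).
#' @param edge_threshold Minimum Sobel gradient magnitude (on a 0-1
#'   intensity scale, so a hard step edge has magnitude about 1) for a pixel
#'   to vote.
#' @param score_floor Minimum normalized accumulator score (votes divided by
#'   the circle circumference) for a peak to count as a detection.
#' @return A data frame with one row per detection and columns `x`, `y`
#'   (subpixel centre), `radius` (px) and `score`, ordered by decreasing
#'   score. Fewer than `n_expected` peaks above the floor raises an error of
#'   class `blockface_detection_error` carrying `n_found`.
#' @export
detect_markers <- function(image, radius_range, n_expected = 4L,
                           edge_threshold = 0.1, score_floor = 0.05) {
  stopifnot(is_raster_image(image), length(radius_range) == 2L,
            radius_range[1] <= radius_range[2])
  d <- dim(image$pixels)
  h <- d[1]; w <- d[2]
  if (radius_range[1] <= 0 || radius_range[2] >= min(w, h) / 4)
    stop("`radius_range` must lie within (0, min(image dims)/4)")

  gray <- luminance601(image$pixels) / 255
  inv <- 1 - gray
  g <- sobel_gradients(inv)
  mag <- sqrt(g$gx^2 + g$gy^2)
  edge <- which(mag > edge_threshold)

  radii <- seq(floor(radius_range[1]), ceiling(radius_range[2]))
  cand <- collect_hough_candidates(edge, mag, g, radii, w, h, score_floor)

  if (nrow(cand)) {
    # strongest first; deterministic tie-break on (y, x)
    cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
    keep <- nms_keep(cand, min_dist = 2 * max(radii))
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) < n_expected)
    bf_stop(sprintf(
      "found %d circle peak(s) above the score floor, expected %d",
      nrow(cand), n_expected),
      "blockface_detection_error", n_found = nrow(cand))
  cand <- cand[seq_len(n_expected), , drop = FALSE]

  for (k in seq_len(nrow(cand))) {
    ref <- refine_center(gray * 255, cand$x[k], cand$y[k], cand$radius[k])
    cand$x[k] <- ref[1]; cand$y[k] <- ref[2]
  }
  rownames(cand) <- NULL
  cand
}

# Sobel gradients of a matrix, normalized so a unit step edge has
# magnitude ~1; borders handled by edge replication.
sobel_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, 1:(h - 1)), ]; dn <- m[c(2:h, h), ]
  lf <- function(mm) mm[, c(1, 1:(w - 1))]
  rt <- function(mm) mm[, c(2:w, w)]
  gx <- (rt(up) + 2 * rt(m) + rt(dn) - lf(up) - 2 * lf(m) - lf(dn)) / 8
  gy <- ((lf(dn) + 2 * dn + rt(dn)) - (lf(up) + 2 * up + rt(up))) / 8
  list(gx = gx, gy = gy)
}

# One accumulator per radius (votes cast along the gradient direction),
# 3 x 3 box smoothing, local maxima above the floor.
collect_hough_candidates <- function(edge, mag, g, radii, w, h, score_floor) {
  if (length(edge) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      radius = numeric(0), score = numeric(0)))
  m <- mag[edge]
  ux <- g$gx[edge] / m
  uy <- g$gy[edge] / m
  ex <- (edge - 1L) %/% h   # 0-based x
  ey <- (edge - 1L) %% h    # 0-based y
  out <- vector("list", length(radii))
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    cx <- as.integer(round(ex + r * ux))
    cy <- as.integer(round(ey + r * uy))
    ok <- cx >= 0L & cx < w & cy >= 0L & cy < h
    if (!any(ok)) next
    idx <- cy[ok] + cx[ok] * h + 1L
    acc <- numeric(w * h)
    tt <- rowsum(m[ok], idx)
    acc[as.integer(rownames(tt))] <- tt
    accm <- box3(matrix(acc, h, w))
    norm <- 2 * pi * r
    floor_votes <- score_floor * norm
    peaks <- which(accm > floor_votes & accm == box3max(accm))
    if (length(peaks) == 0L) next
    # cap per-radius candidates to the strongest 32
    if (length(peaks) > 32L) peaks <- peaks[order(-accm[peaks])][1:32]
    out[[ri]] <- data.frame(x = (peaks - 1L) %/% h, y = (peaks - 1L) %% h,
                            radius = r, score = accm[peaks] / norm)
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  s <- m
  s[-1, ] <- s[-1, ] + m[-h, ]
  s[-h, ] <- s[-h, ] + m[-1, ]
  s2 <- s
  s2[, -1] <- s2[, -1] + s[, -w]
  s2[, -w] <- s2[, -w] + s[, -1]
  s2
}

# 3 x 3 neighbourhood maximum (for local-maximum detection)
box3max <- function(m) {
  h <- nrow(m); w <- ncol(m)
  s <- m
  s[-1, ] <- pmax(s[-1, ], m[-h, ])
  s[-h, ] <- pmax(s[-h, ], m[-1, ])
  s2 <- s
  s2[, -1] <- pmax(s2[, -1], s[, -w])
  s2[, -w] <- pmax(s2[, -w], s[, -1])
  s2
}

nms_keep <- function(cand, min_dist) {
  keep <- logical(nrow(cand))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kx) &&
        any((cand$x[i] - kx)^2 + (cand$y[i] - ky)^2 < min_dist^2)) next
    keep[i] <- TRUE
    kx <- c(kx, cand$x[i]); ky <- c(ky, cand$y[i])
  }
  keep
}

# Subpixel centre: darkness-weighted centroid of below-threshold pixels
# within the detected circle; Otsu threshold over interior + annulus.
refine_center <- function(gray255, cx, cy, r) {
  h <- nrow(gray255); w <- ncol(gray255)
  hw <- ceiling(1.8 * r)
  xs <- max(0, floor(cx - hw)):min(w - 1, ceiling(cx + hw))
  ys <- max(0, floor(cy - hw)):min(h - 1, ceiling(cy + hw))
  win <- gray255[ys + 1L, xs + 1L, drop = FALSE]
  gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  d2 <- (gx - cx)^2 + (gy - cy)^2
  region <- d2 <= (1.8 * r)^2                 # interior + annulus
  thr <- 255 * EBImage::otsu(EBImage::Image(win[region] / 255),
                             range = c(0, 1))
  inside <- d2 <= (1.15 * r)^2 & win < thr
  wgt <- (thr - win) * inside
  sw <- sum(wgt)
  if (sw <= 0) return(c(cx, cy))
  c(sum(wgt * gx) / sw, sum(wgt * gy) / sw)
}

#' Label four marker detections by block corner
#'
#' Assigns each detection the label of the image quadrant (relative to the
#' image centre) it falls in: `TL`, `TR`, `BL`, `BR`. Labelling is
#' order-invariant and deterministic.
#'
#' @param detections Data frame with columns `x`, `y`, `radius`, `score`
#'   (as returned by [detect_markers()]); exactly four rows.
#' @param image_dims Length-2 `(width, height)` of the image in px.
#' @param slice_index Slice index stored in the result.
#' @return A `blockface_fiducials` object: the detections with a `corner`
#'   column, ordered TL, TR, BL, BR.
#' @export
assign_corners <- function(detections, image_dims, slice_index = 0L) {
  stopifnot(is.data.frame(detections), nrow(detections) == 4L,
            length(image_dims) == 2L)
  cx <- (image_dims[1] - 1) / 2
  cy <- (image_dims[2] - 1) / 2
  corner <- paste0(ifelse(detections$y < cy, "T", "B"),
                   ifelse(detections$x < cx, "L", "R"))
  dup <- corner[duplicated(corner)]
  if (length(dup))
    bf_stop(paste0("two detections fall in the same quadrant: ",
                   paste(unique(dup), collapse = ", ")),
            "blockface_corner_ambiguity", quadrant = unique(dup))
  ord <- match(c("TL", "TR", "BL", "BR"), corner)
  out <- detections[ord, c("x", "y", "radius", "score")]
  out$corner <- c("TL", "TR", "BL", "BR")
  out <- out[, c("corner", "x", "y", "radius", "score")]
  fiducial_set(slice_index, out, image_dims)
}

#' Labeled fiducial set for one image
#'
#' @param slice_index 0-based slice index.
#' @param markers Data frame with columns `corner` (`TL`,`TR`,`BL`,`BR`,
#'   one row each), `x`, `y`, `radius`, `score`.
#' @param image_dims Length-2 `(width, height)` in px used to validate
#'   quadrant membership and border clearance.
#' @return A `blockface_fiducials` object (data frame subclass with
#'   attributes `slice_index` and `image_dims`).
#' @export
fiducial_set <- function(slice_index, markers, image_dims) {
  stopifnot(is.data.frame(markers),
            all(c("corner", "x", "y", "radius", "score") %in% names(markers)))
  if (!setequal(markers$corner, c("TL", "TR", "BL", "BR")) ||
      nrow(markers) != 4L)
    stop("`markers` must contain exactly one row per corner TL, TR, BL, BR")
  markers <- markers[match(c("TL", "TR", "BL", "BR"), markers$corner), ]
  cx <- (image_dims[1] - 1) / 2
  cy <- (image_dims[2] - 1) / 2
  expect <- paste0(ifelse(markers$y < cy, "T", "B"),
                   ifelse(markers$x < cx, "L", "R"))
  if (!all(expect == markers$corner))
    stop("marker(s) ", paste(markers$corner[expect != markers$corner],
                             collapse = ", "),
         " do not lie in their labeled quadrant")
  bad <- markers$x < markers$radius | markers$y < markers$radius |
    markers$x > image_dims[1] - 1 - markers$radius |
    markers$y > image_dims[2] - 1 - markers$radius
  if (any(bad))
    stop("marker(s) ", paste(markers$corner[bad], collapse = ", "),
         " lie closer to the image border than their radius")
  rownames(markers) <- markers$corner
  structure(markers, class = c("blockface_fiducials", "data.frame"),
            slice_index = as.integer(slice_index),
            image_dims = as.numeric(image_dims))
}

#' @rdname fiducial_set
#' @param x Object to query.
#' @return `fiducial_centers` returns the 4 x 2 matrix of centres (rows
#'   TL, TR, BL, BR).
#' @export
fiducial_centers <- function(x) {
  stopifnot(inherits(x, "blockface_fiducials"))
  m <- cbind(x$x, x$y)
  rownames(m) <- x$corner
  m
}

#' Detect and corner-label the four fiducial markers of one image
#'
#' Convenience wrapper: [detect_markers()] followed by [assign_corners()].
#'
#' @inheritParams detect_markers
#' @param slice_index Slice index stored in the result.
#' @param ... Passed on to [detect_markers()].
#' @return A [fiducial_set()].
#' @export
detect_fiducials <- function(image, radius_range, slice_index = 0L, ...) {
  det <- detect_markers(image, radius_range, n_expected = 4L, ...)
  d <- dim(image$pixels)
  assign_corners(det, c(d[2], d[1]), slice_index)
}

#' Export fiducial detections of a stack as CSV
#'
#' @param fiducials List of [fiducial_set()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly. Columns: slice_index, corner, x, y, radius,
#'   score.
#' @export
fiducials_to_csv <- function(fiducials, path) {
  rows <- lapply(fiducials, function(f) {
    data.frame(slice_index = attr(f, "slice_index"), corner = f$corner,
               x = f$x, y = f$y, radius = f$radius, score = f$score)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
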