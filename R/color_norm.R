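#' Reference patch region for white balancing
#'
#' A small rectangle (default 25 x 25 px) placed over an area containing
#' only paraffin, used as the neutral ("true white") reference. Coordinates
#' are 0-based pixel indices in the aligned image frame, so the same patch
#' stays on paraffin across the whole coregistered stack.
#'
#' @param x,y Top-left corner (0-based px).
#' @param w,h Patch size in px (default 25 x 25).
#' @return An object of class `blockface_patch`.
#' @export
patch_region <- function(x, y, w = 25L, h = 25L) {
  stopifnot(x >= 0, y >= 0, w >= 1, h >= 1)
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "blockface_patch")
}

# Extract the patch pixels as an n x 3 matrix; errors if out of bounds.
patch_pixels <- function(image, patch) {
  stopifnot(is_raster_image(image), inherits(patch, "blockface_patch"))
  d <- dim(image$pixels)
  if (patch$x + patch$w > d[2] || patch$y + patch$h > d[1])
    stop(sprintf("patch (%d,%d,%dx%d) extends outside the %d x %d image",
                 patch$x, patch$y, patch$w, patch$h, d[2], d[1]))
  rows <- patch$y + seq_len(patch$h)
  cols <- patch$x + seq_len(patch$w)
  apply(image$pixels[rows, cols, , drop = FALSE], 3, c)
}

#' Patch-referenced white balance
#'
#' Treats the paraffin patch as the true neutral reference: per-channel
#' gains `g_c = L / m_c` are computed from the patch channel means `m_c`
#' and their luminance `L = (m_R + m_G + m_B) / 3`, and applied to the whole
#' image (rounded, clipped to `[0, 255]`). After the operation the patch is
#' neutral (equal channel means up to quantization) at unchanged overall
#' luminance, so the image is rebalanced without being blown out.
#'
#' @param image A [raster_image()].
#' @param patch A [patch_region()] lying fully inside the image. If the
#'   patch channel standard deviation exceeds `sd_ceiling` a warning is
#'   issued — the patch probably covers more than paraffin.
#' @param sd_ceiling Warning threshold on the patch channel standard
#'   deviation (intensity units).
#' @return The rebalanced [raster_image()].
#' @export
white_balance <- function(image, patch, sd_ceiling = 12) {
  pp <- patch_pixels(image, patch)
  m <- colMeans(pp)
  if (any(m < 1))
    stop("patch channel mean below 1: the patch is (near-)black, not paraffin")
  if (max(apply(pp, 2, stats::sd)) > sd_ceiling)
    warning(sprintf(
      "patch channel sd exceeds %.3g: the patch may not be pure paraffin",
      sd_ceiling))
  g <- mean(m) / m
  out <- image$pixels * rep(g, each = prod(dim(image$pixels)[1:2]))
  raster_image(out, image$pixel_size_mm)
}

#' Saturation enhancement about the per-pixel luminance
#'
#' Moves every channel away from (or towards) the pixel's ITU-R BT.601
#' luminance: `out = gray + factor * (in - gray)`. Factor 1 is the
#' identity, 0 full desaturation, above 1 boosts colour saturation — a
#' cosmetic step that makes injected labeling media easier to tell apart on
#' screen.
#'
#' @param image A [raster_image()].
#' @param factor Non-negative finite saturation factor.
#' @return The enhanced [raster_image()].
#' @export
enhance_color <- function(image, factor = 1.3) {
  stopifnot(is_raster_image(image))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor))
    stop("`factor` must be a finite scalar")
  if (factor < 0) stop("`factor` must be non-negative")
  px <- image$pixels
  gray <- luminance601(px)
  out <- array(0, dim = dim(px))
  # c + (f-1)*(c-gray) is algebraically gray + f*(c-gray) but exactly the
  # identity when factor == 1
  for (ch in 1:3) out[, , ch] <- px[, , ch] + (factor - 1) * (px[, , ch] - gray)
  raster_image(out, image$pixel_size_mm)
}

#' Summary statistics of one image channel
#'
#' @param mean,sd Channel mean and standard deviation (intensity units).
#' @param n Number of pixels the statistics were computed from.
#' @param channel Channel identifier (e.g. `"V"`).
#' @return An object of class `blockface_channel_stats`.
#' @export
channel_stats <- function(mean, sd, n, channel = "V") {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 1)
  structure(list(channel = channel, mean = as.numeric(mean),
                 sd = as.numeric(sd), n = as.integer(n)),
            class = "blockface_channel_stats")
}

#' @rdname channel_stats
#' @param image A [raster_image()] to summarize.
#' @return `v_channel_stats` returns the stats of the image's HSV value
#'   channel (V = max(R, G, B), on the 0-255 scale).
#' @export
v_channel_stats <- function(image) {
  stopifnot(is_raster_image(image))
  v <- pmax(image$pixels[, , 1], pmax(image$pixels[, , 2],
                                      image$pixels[, , 3]))
  channel_stats(mean(v), stats::sd(v), length(v), "V")
}

#' Brightness transfer via V-channel statistics matching
#'
#' Equalizes exposure across the stack: the image is converted to HSV
#' (hexcone model on `[0, 255]` channels, `V = max(R, G, B)`), the value
#' channel is linearly remapped to the reference's first and second moments,
#' `V' = (V - mu_src) * (sd_ref / sd_src) + mu_ref`, clipped to the valid
#' range, and the image is converted back to RGB with hue and saturation
#' untouched.
#'
#' @param image A [raster_image()]; must not be constant (source V standard
#'   deviation must be positive).
#' @param ref A [channel_stats()] holding the reference V mean and sd
#'   (typically from the stack's first image via [v_channel_stats()]).
#' @return The brightness-matched [raster_image()].
#' @export
transfer_brightness <- function(image, ref) {
  stopifnot(is_raster_image(image), inherits(ref, "blockface_channel_stats"))
  hsv <- rgb_to_hsv255(image$pixels)
  mu_s <- mean(hsv$v)
  sd_s <- stats::sd(hsv$v)
  if (sd_s == 0)
    stop("source V channel is constant (sd = 0); cannot transfer brightness")
  v2 <- (hsv$v - mu_s) * (ref$sd / sd_s) + ref$mean
  v2[v2 < 0] <- 0
  v2[v2 > 255] <- 255
  raster_image(hsv_to_rgb255(hsv$h, hsv$s, v2), image$pixel_size_mm)
}

# Hexcone RGB -> HSV on [0, 255] channels: h in [0, 6), s in [0, 1],
# v in [0, 255].
rgb_to_hsv255 <- function(px) {
  d <- dim(px)
  r <- matrix(px[, , 1], d[1], d[2])
  g <- matrix(px[, , 2], d[1], d[2])
  b <- matrix(px[, , 3], d[1], d[2])
  v <- pmax(r, g, b)
  m <- pmin(r, g, b)
  c <- v - m
  s <- ifelse(v > 0, c / v, 0)
  h <- matrix(0, nrow(r), ncol(r))
  nz <- c > 0
  rmax <- nz & v == r
  gmax <- nz & !rmax & v == g
  bmax <- nz & !rmax & !gmax
  h[rmax] <- ((g[rmax] - b[rmax]) / c[rmax]) %% 6
  h[gmax] <- (b[gmax] - r[gmax]) / c[gmax] + 2
  h[bmax] <- (r[bmax] - g[bmax]) / c[bmax] + 4
  list(h = h, s = s, v = v)
}

hsv_to_rgb255 <- function(h, s, v) {
  c <- v * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- v - c
  hi <- pmin(floor(h), 5)
  r <- ifelse(hi == 0 | hi == 5, c, ifelse(hi == 1 | hi == 4, x, 0))
  g <- ifelse(hi == 0 | hi == 3, x, ifelse(hi == 1 | hi == 2, c, 0))
  b <- ifelse(hi == 2 | hi == 5, x, ifelse(hi == 3 | hi == 4, c, 0))
  out <- array(0, dim = c(nrow(h), ncol(h), 3))
  out[, , 1] <- r + m
  out[, , 2] <- g + m
  out[, , 3] <- b + m
  out
}
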