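#' 2D RGB raster with a physical pixel size
#'
#' The basic image container of the package: an `H x W x 3` array of 8-bit
#' channel intensities (stored as integers in `[0, 255]`) plus the physical
#' edge length of one (square) pixel in millimetres. Pixel centres sit at
#' integer coordinates, 0-based, origin at the top-left corner, x rightward,
#' y downward.
#'
#' @param pixels Numeric array of dimension `H x W x 3` with values in
#'   `[0, 255]`. Non-integer values are quantized with round-half-up.
#' @param pixel_size_mm Positive scalar; physical size of one pixel in mm.
#' @return An object of class `blockface_raster`: a list with elements
#'   `pixels` (integer array) and `pixel_size_mm`.
#' @examples
#' img <- raster_image(array(128, dim = c(10, 20, 3)), pixel_size_mm = 0.1)
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, pixel_size_mm) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("image must have at least one row and one column")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a positive finite scalar")
  px <- quantize8(pixels)
  structure(list(pixels = px, pixel_size_mm = as.numeric(pixel_size_mm)),
            class = "blockface_raster")
}

#' @export
print.blockface_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<blockface_raster> %d x %d px, %.4g mm/px (%.4g x %.4g mm)\n",
              d[2], d[1], x$pixel_size_mm,
              d[2] * x$pixel_size_mm, d[1] * x$pixel_size_mm))
  invisible(x)
}

#' @rdname raster_image
#' @param x Object to test.
#' @export
is_raster_image <- function(x) inherits(x, "blockface_raster")

# Round-half-up quantization to 8-bit integers, clipped to [0, 255].
quantize8 <- function(x) {
  x <- floor(x + 0.5)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' @rdname raster_image
#' @export
raster_dims <- function(x) {
  stopifnot(is_raster_image(x))
  c(w = dim(x$pixels)[2], h = dim(x$pixels)[1])
}

# ITU-R BT.601 luma of an H x W x 3 numeric array -> H x W matrix.
luminance601 <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Median colour of a border ring
#'
#' Per-channel median over a ring of pixels along the image border. On
#' blockface photographs the border is paraffin, so this approximates the
#' paraffin background colour and is the default fill for resampled
#' out-of-frame pixels.
#'
#' @param image A [raster_image()].
#' @param ring Ring width in pixels (default 10, capped at the image size).
#' @return Numeric length-3 RGB vector.
#' @export
border_median_color <- function(image, ring = 10L) {
  stopifnot(is_raster_image(image))
  d <- dim(image$pixels)
  ring <- max(1L, min(as.integer(ring), floor(min(d[1:2]) / 2)))
  h <- d[1]; w <- d[2]
  mask <- matrix(FALSE, h, w)
  mask[c(seq_len(ring), h - seq_len(ring) + 1L), ] <- TRUE
  mask[, c(seq_len(ring), w - seq_len(ring) + 1L)] <- TRUE
  vapply(1:3, function(ch) stats::median(image$pixels[, , ch][mask]),
         numeric(1))
}

#' Read and write rasters as PNG (or JPEG) files
#'
#' Thin wrappers around the `png` (and, when available, `jpeg`) packages that
#' attach the physical pixel size, which image files do not carry.
#'
#' @param path File path; format chosen by extension (`.png`, `.jpg`/`.jpeg`).
#' @param pixel_size_mm Physical pixel size to attach to the raster read.
#' @return `read_raster` returns a [raster_image()]; `write_raster` returns
#'   `path` invisibly. PNG output is lossless.
#' @export
read_raster <- function(path, pixel_size_mm) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the `jpeg` package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (dim(arr)[3] == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  raster_image(arr * 255, pixel_size_mm)
}

#' @rdname read_raster
#' @param image A [raster_image()].
#' @export
write_raster <- function(image, path) {
  stopifnot(is_raster_image(image))
  ext <- tolower(tools::file_ext(path))
  arr <- image$pixels / 255
  switch(ext,
    png = png::writePNG(arr, path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("writing JPEG requires the `jpeg` package")
      jpeg::writeJPEG(arr, path, quality = 0.95)
    },
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}

# Condition helper: classed errors carrying structured data.
bf_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "blockface_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
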