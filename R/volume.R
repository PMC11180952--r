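#' Lanczos downsampling to a target physical resolution
#'
#' Resamples an image to a coarser pixel grid with a separable Lanczos
#' windowed-sinc filter (a = 3). The kernel support is stretched by the
#' downsampling factor (proper anti-aliasing), weights are renormalized at
#' the borders, and output dimensions are
#' `round(dim * pixel_size / target)`, so the physical extent is preserved
#' to within one output pixel. Requesting a finer grid than the input is an
#' error: upsampling blockfaces is never wanted. When the target equals the
#' current pixel size the input is returned unchanged.
#'
#' @param image A [raster_image()].
#' @param target_mm Target pixel size in mm, at least the current one.
#' @return A [raster_image()] with `pixel_size_mm = target_mm`.
#' @export
downsample <- function(image, target_mm) {
  stopifnot(is_raster_image(image), is.numeric(target_mm),
            length(target_mm) == 1L, is.finite(target_mm))
  ps <- image$pixel_size_mm
  if (target_mm < ps - 1e-12)
    stop(sprintf(
      "target %.6g mm is finer than the current %.6g mm pixel: upsampling is not supported",
      target_mm, ps))
  if (abs(target_mm - ps) <= 1e-12) return(image)
  d <- dim(image$pixels)
  h_in <- d[1]; w_in <- d[2]
  w_out <- max(1L, as.integer(round(w_in * ps / target_mm)))
  h_out <- max(1L, as.integer(round(h_in * ps / target_mm)))
  wy <- lanczos_operator(h_in, h_out)
  wx <- lanczos_operator(w_in, w_out)
  out <- array(0, dim = c(h_out, w_out, 3))
  for (ch in 1:3)
    out[, , ch] <- as.matrix(wy %*% image$pixels[, , ch] %*% Matrix::t(wx))
  raster_image(out, target_mm)
}

# Sparse n_out x n_in Lanczos-3 resampling operator with rows summing to 1.
lanczos_operator <- function(n_in, n_out) {
  a <- 3
  sigma <- n_in / n_out                 # > 1 for downsampling
  centers <- ((0:(n_out - 1)) + 0.5) * sigma - 0.5
  ii <- jj <- vv <- vector("list", n_out)
  for (o in seq_len(n_out)) {
    c0 <- centers[o]
    k <- max(0, ceiling(c0 - a * sigma)):min(n_in - 1, floor(c0 + a * sigma))
    t <- (k - c0) / sigma
    w <- sinc(t) * sinc(t / a)
    w <- w / sum(w)
    ii[[o]] <- rep(o, length(k))
    jj[[o]] <- k + 1
    vv[[o]] <- w
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n_out, n_in))
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Isotropic 3D RGB volume grid
#'
#' Container for a reconstructed volume: a `D x H x W x 3` voxel array
#' (slice, row, column, channel) of 8-bit intensities with a single
#' isotropic voxel edge length. Slice index 0 is the first photographed
#' blockface; the index increases along the cutting direction, which the
#' NIfTI affine maps to +z of a right-handed frame.
#'
#' @param voxels Numeric `D x H x W x 3` array of intensities in
#'   `[0, 255]`.
#' @param voxel_size_mm Positive scalar voxel edge length (identical on all
#'   three axes).
#' @return An object of class `blockface_volume`.
#' @export
volume_grid <- function(voxels, voxel_size_mm) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L || dim(voxels)[4] != 3L)
    stop("`voxels` must be a D x H x W x 3 array")
  stopifnot(is.numeric(voxel_size_mm), length(voxel_size_mm) == 1L,
            is.finite(voxel_size_mm), voxel_size_mm > 0)
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "blockface_volume")
}

#' @export
print.blockface_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<blockface_volume> %d slices x %d x %d px RGB, %.4g mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  invisible(x)
}

#' Stack preprocessed blockface images into an isotropic volume
#'
#' The volume is isotropic by construction, not by resampling: the in-plane
#' pixel size of every image must already equal the slice spacing (which is
#' why the pipeline downsamples to the slice spacing first). A mismatch is
#' an error telling the user to adjust the downsampling target or the
#' photograph interval, rather than a silent interpolation.
#'
#' @param stack Ordered list of [raster_image()]s sharing dimensions and
#'   pixel size.
#' @param spacing_mm Physical spacing between consecutive slices in mm.
#' @return A [volume_grid()] with one slab per input image.
#' @export
build_volume <- function(stack, spacing_mm) {
  stopifnot(length(stack) >= 1L, all(vapply(stack, is_raster_image,
                                            logical(1))))
  d0 <- dim(stack[[1]]$pixels)
  for (i in seq_along(stack)) {
    di <- dim(stack[[i]]$pixels)
    if (!identical(di, d0))
      bf_stop(sprintf(
        "slice %d is %d x %d px but slice 0 is %d x %d px: mixed dimensions",
        i - 1L, di[2], di[1], d0[2], d0[1]), "blockface_mixed_dims")
  }
  ps <- stack[[1]]$pixel_size_mm
  if (abs(ps - spacing_mm) > 1e-9)
    bf_stop(sprintf(paste0(
      "anisotropic voxels: in-plane resolution %.6g mm differs from slice ",
      "spacing %.6g mm; adjust the downsampling target or the photograph ",
      "interval"), ps, spacing_mm), "blockface_anisotropy_error")
  vox <- array(0L, dim = c(length(stack), d0[1], d0[2], 3L))
  for (i in seq_along(stack)) vox[i, , , ] <- stack[[i]]$pixels
  volume_grid(vox, spacing_mm)
}

#' Write / read an RGB volume as NIfTI-1
#'
#' `write_nifti` serializes a [volume_grid()] with `pixdim` set to the
#' isotropic voxel size on all three spatial axes and an affine mapping the
#' slice index to +z of a right-handed frame. The default encoding is the
#' NIfTI RGB24 datatype (one 3-byte voxel per site, rendered in colour by
#' viewers that support it); `encoding = "channels"` writes a plain 4-D
#' uint8 volume with the channels as a fourth dimension, a fallback for
#' viewers without RGB support. Both encodings round-trip 8-bit data
#' losslessly.
#'
#' @param vol A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param encoding `"rgb"` (default) or `"channels"`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti_volume`
#'   returns a [volume_grid()].
#' @export
write_nifti <- function(vol, path, encoding = c("rgb", "channels")) {
  stopifnot(inherits(vol, "blockface_volume"))
  encoding <- match.arg(encoding)
  d <- dim(vol$voxels)  # D, H, W, 3
  # NIfTI axis order: x = image column, y = image row, z = slice
  xyz <- function(ch) aperm(vol$voxels[, , , ch, drop = TRUE],
                            c(3L, 2L, 1L))
  img <- if (encoding == "rgb") {
    RNifti::rgbArray(xyz(1), xyz(2), xyz(3), dim = c(d[3], d[2], d[1]))
  } else {
    arr <- array(0L, dim = c(d[3], d[2], d[1], 3L))
    for (ch in 1:3) arr[, , , ch] <- xyz(ch)
    arr
  }
  nii <- RNifti::asNifti(img)
  if (encoding == "rgb") {
    RNifti::pixdim(nii) <- rep(vol$voxel_size_mm, 3L)
    RNifti::writeNifti(nii, path)
  } else {
    RNifti::pixdim(nii) <- c(rep(vol$voxel_size_mm, 3L), 1)
    RNifti::writeNifti(nii, path, datatype = "uint8")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(nii)
  vs <- RNifti::pixdim(nii)
  if (hdr$datatype == 128L) {  # RGB24
    ch <- RNifti::channels(nii, c("red", "green", "blue"))
    d <- dim(ch)  # W, H, D, 3
    vox <- array(0L, dim = c(d[3], d[2], d[1], 3L))
    for (k in 1:3) vox[, , , k] <- aperm(ch[, , , k, drop = TRUE], c(3, 2, 1))
    vs <- vs[1:3]
  } else {
    arr <- as.array(nii)
    if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
      stop("NIfTI file is neither RGB24 nor a 4-D three-channel volume")
    d <- dim(arr)
    vox <- array(0L, dim = c(d[3], d[2], d[1], 3L))
    for (k in 1:3) vox[, , , k] <- aperm(arr[, , , k, drop = TRUE], c(3, 2, 1))
    vs <- vs[1:3]
  }
  if (max(vs) - min(vs) > 1e-5)
    warning("volume is not isotropic: pixdim = ", paste(signif(vs, 6),
                                                        collapse = " x "))
  volume_grid(vox, vs[1])
}

#' Classify volume voxels into injection territories by dominant channel
#'
#' Assigns each voxel the territory whose labeling colour dominates it:
#' the voxel's brightest channel is matched against the dominant channel of
#' each territory colour of the phantom (for the default phantom: blue,
#' red, green media). A quality-control helper for synthetic
#' reconstructions.
#'
#' @param vol A [volume_grid()].
#' @param phantom The [phantom_spec()] whose territory colours define the
#'   mapping.
#' @return Integer `D x H x W` array of territory labels (1-3).
#' @export
classify_territories <- function(vol, phantom) {
  stopifnot(inherits(vol, "blockface_volume"),
            inherits(phantom, "blockface_phantom"))
  dom <- apply(phantom$territory_colors, 1, which.max)
  if (anyDuplicated(dom))
    stop("territory colours do not have distinct dominant channels")
  d <- dim(vol$voxels)
  r <- vol$voxels[, , , 1]; g <- vol$voxels[, , , 2]; b <- vol$voxels[, , , 3]
  argmax <- array(1L, dim = d[1:3])
  argmax[g > r & g >= b] <- 2L
  argmax[b > r & b > g] <- 3L
  lab <- array(match(argmax, dom), dim = d[1:3])
  lab
}
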