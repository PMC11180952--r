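#' Acquisition geometry of a blockface photography rig
#'
#' Bundles the fixed parameters of the cutting/photography set-up: the
#' camera field of view, the sensor resolution, the microtome cut thickness,
#' how many cuts pass between consecutive photographs, and the target voxel
#' size for the reconstructed volume. The defaults describe a rig
#' photographing a 150 x 100 mm field at 1500 x 1000 px (0.1 mm pixels) with
#' 20 um cuts and a photograph every tenth cut; `resolution_px = c(6000, 4000)`
#' gives the full-resolution 0.025 mm geometry of a DSLR with a macro lens.
#'
#' @param fov_mm Length-2 numeric, field of view `(width, height)` in mm.
#' @param resolution_px Length-2 integer, sensor resolution `(width, height)`
#'   in px. Must give square pixels together with `fov_mm`.
#' @param cut_thickness_um Microtome cut thickness in micrometres.
#' @param photo_every_k Photograph every k-th cut (integer >= 1).
#' @param target_voxel_mm Isotropic voxel size of the reconstructed volume.
#' @return An object of class `blockface_acquisition` with the validated
#'   fields plus the derived `pixel_size_mm` and `slice_spacing_mm`.
#' @examples
#' acq <- acquisition_params(resolution_px = c(6000, 4000))
#' acq$pixel_size_mm    # 0.025
#' acq$slice_spacing_mm # 0.2
#' @export
acquisition_params <- function(fov_mm = c(150, 100),
                               resolution_px = c(1500, 1000),
                               cut_thickness_um = 20,
                               photo_every_k = 10L,
                               target_voxel_mm = 0.2) {
  stopifnot(length(fov_mm) == 2L, length(resolution_px) == 2L)
  vals <- c(fov_mm, resolution_px, cut_thickness_um, photo_every_k,
            target_voxel_mm)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all acquisition parameters must be strictly positive and finite")
  if (photo_every_k < 1 || photo_every_k != round(photo_every_k))
    stop("`photo_every_k` must be an integer >= 1")
  ps <- compute_pixel_size(fov_mm, resolution_px)
  structure(list(
    fov_mm = as.numeric(fov_mm),
    resolution_px = as.integer(round(resolution_px)),
    cut_thickness_um = as.numeric(cut_thickness_um),
    photo_every_k = as.integer(photo_every_k),
    target_voxel_mm = as.numeric(target_voxel_mm),
    pixel_size_mm = ps,
    slice_spacing_mm = compute_slice_spacing(cut_thickness_um, photo_every_k)
  ), class = "blockface_acquisition")
}

#' @export
print.blockface_acquisition <- function(x, ...) {
  cat(sprintf(paste0(
    "<blockface_acquisition> FOV %g x %g mm @ %d x %d px (%g mm/px)\n",
    "  cuts %g um, photo every %d -> slice spacing %g mm; target voxel %g mm\n"),
    x$fov_mm[1], x$fov_mm[2], x$resolution_px[1], x$resolution_px[2],
    x$pixel_size_mm, x$cut_thickness_um, x$photo_every_k,
    x$slice_spacing_mm, x$target_voxel_mm))
  invisible(x)
}

#' Physical pixel size from field of view and resolution
#'
#' `pixel = fov_width / width_px`, requiring square pixels: the width and
#' height ratios must agree to within 1e-9 mm.
#'
#' @param fov_mm Length-2 numeric `(width, height)` in mm.
#' @param resolution_px Length-2 numeric `(width, height)` in px.
#' @return Pixel edge length in mm.
#' @examples
#' compute_pixel_size(c(150, 100), c(6000, 4000)) # 0.025
#' @export
compute_pixel_size <- function(fov_mm, resolution_px) {
  stopifnot(length(fov_mm) == 2L, length(resolution_px) == 2L,
            all(is.finite(c(fov_mm, resolution_px))),
            all(c(fov_mm, resolution_px) > 0))
  rw <- fov_mm[1] / resolution_px[1]
  rh <- fov_mm[2] / resolution_px[2]
  if (abs(rw - rh) > 1e-9)
    bf_stop(sprintf(
      "non-square pixel geometry: width gives %.10g mm/px, height %.10g mm/px",
      rw, rh), "blockface_geometry_error", width_ratio = rw, height_ratio = rh)
  rw
}

#' Physical spacing between photographed blockfaces
#'
#' Photographing every k-th cut of thickness t um puts consecutive
#' photographs `k * t / 1000` mm apart along the cutting axis.
#'
#' @param cut_thickness_um Cut thickness in micrometres.
#' @param photo_every_k Photograph every k-th cut.
#' @return Slice spacing in mm.
#' @examples
#' compute_slice_spacing(20, 10) # 0.2
#' @export
compute_slice_spacing <- function(cut_thickness_um, photo_every_k) {
  stopifnot(is.finite(cut_thickness_um), cut_thickness_um > 0,
            is.finite(photo_every_k), photo_every_k >= 1)
  cut_thickness_um * photo_every_k / 1000
}
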