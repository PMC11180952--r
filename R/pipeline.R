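#' Pipeline configuration
#'
#' Assembles and validates the configuration for the whole reconstruction
#' pipeline. Every section has complete defaults mirroring the documented
#' acquisition set-up (150 x 100 mm field, 20 um cuts, photograph every
#' tenth cut, 0.2 mm target voxel, 25 x 25 px paraffin patch); passing a
#' key that does not exist in the defaults is an error, so typos in config
#' files fail loudly instead of being ignored.
#'
#' @param acquisition,phantom,jitter,fiducials,alignment,color,volume
#'   Named lists overriding the defaults of each section (see Details).
#' @param seed Integer seed used by the `simulate` stage.
#' @details Sections and their defaults:
#' * `acquisition`: arguments of [acquisition_params()].
#' * `phantom`: arguments of [phantom_spec()] (simulation only).
#' * `jitter`: arguments of [jitter_spec()] (simulation only).
#' * `fiducials`: `marker_radius_mm` (2.5), `radius_factor` (`c(0.7, 1.3)`,
#'   multiplied by the nominal marker radius in px to get the Hough search
#'   range), `edge_threshold` (0.1), `score_floor` (0.05).
#' * `alignment`: `joint` (`FALSE`: two-stage magnification + rigid fit).
#' * `color`: `patch` (`x`, `y`, `w`, `h` in the aligned, downsampled
#'   frame), `enhance_factor` (1.3), `brightness_reference`
#'   (`"first"` or `"global"`).
#' * `volume`: `encoding` (`"rgb"` or `"channels"`).
#' @return An object of class `blockface_config`.
#' @export
pipeline_config <- function(acquisition = list(), phantom = list(),
                            jitter = list(), fiducials = list(),
                            alignment = list(), color = list(),
                            volume = list(), seed = 1L) {
  defaults <- list(
    fiducials = list(marker_radius_mm = 2.5, radius_factor = c(0.7, 1.3),
                     edge_threshold = 0.1, score_floor = 0.05),
    alignment = list(joint = FALSE),
    color = list(patch = list(x = 362L, y = 12L, w = 25L, h = 25L),
                 enhance_factor = 1.3, brightness_reference = "first"),
    volume = list(encoding = "rgb")
  )
  merge_strict <- function(def, user, where) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      stop("unknown config key(s) in `", where, "`: ",
           paste(unknown, collapse = ", "))
    for (nm in names(user)) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(user[[nm]]))
        merge_strict(def[[nm]], user[[nm]], paste0(where, ".", nm))
      else user[[nm]]
    }
    def
  }
  check_args <- function(user, fn, where) {
    unknown <- setdiff(names(user), names(formals(fn)))
    if (length(unknown))
      stop("unknown config key(s) in `", where, "`: ",
           paste(unknown, collapse = ", "))
    user
  }
  acq <- do.call(acquisition_params,
                 check_args(acquisition, acquisition_params, "acquisition"))
  ph <- do.call(phantom_spec, check_args(phantom, phantom_spec, "phantom"))
  jt <- do.call(jitter_spec, check_args(jitter, jitter_spec, "jitter"))
  fid <- merge_strict(defaults$fiducials, fiducials, "fiducials")
  aln <- merge_strict(defaults$alignment, alignment, "alignment")
  col <- merge_strict(defaults$color, color, "color")
  vol <- merge_strict(defaults$volume, volume, "volume")
  stopifnot(col$brightness_reference %in% c("first", "global"),
            vol$encoding %in% c("rgb", "channels"),
            length(fid$radius_factor) == 2L, fid$radius_factor[1] > 0)
  structure(list(acquisition = acq, phantom = ph, jitter = jt,
                 fiducials = fid, alignment = aln, color = col,
                 volume = vol, seed = as.integer(seed)),
            class = "blockface_config")
}

#' @rdname pipeline_config
#' @param path YAML config file; its top-level sections are passed to
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("acquisition", "phantom", "jitter", "fiducials", "alignment",
             "color", "volume", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}

# Hough search range in px for the configured marker radius.
config_radius_range <- function(config) {
  nominal <- config$fiducials$marker_radius_mm /
    config$acquisition$pixel_size_mm
  config$fiducials$radius_factor * nominal
}

bf_logger <- function(log_file = NULL, verbose = TRUE) {
  if (!is.null(log_file))
    dir.create(dirname(log_file), showWarnings = FALSE, recursive = TRUE)
  function(fmt, ...) {
    line <- sprintf(fmt, ...)
    if (verbose) message(line)
    if (!is.null(log_file))
      cat(line, "\n", file = log_file, append = TRUE, sep = "")
    invisible(line)
  }
}

with_stage <- function(stage, slice, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage `%s`, slice %s: %s", stage,
                 if (is.null(slice)) "-" else slice, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Simulate a blockface photography session to disk
#'
#' Generates a synthetic stack under the config's acquisition, phantom and
#' jitter sections and writes it as numbered PNGs plus a ground-truth JSON
#' sidecar.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param n_slices Number of blockfaces to simulate.
#' @param seed RNG seed (default: the config's).
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir, n_slices, seed = config$seed) {
  stopifnot(inherits(config, "blockface_config"))
  stk <- generate_stack(config$acquisition, config$phantom, n_slices,
                        config$jitter, seed = seed)
  write_stack(stk, out_dir)
}

#' Run the full blockface reconstruction pipeline
#'
#' Orchestrates every stage on an input image stack, in fixed order:
#' fiducial detection, magnification + rigid coregistration onto the first
#' image, resampling into the reference frame, Lanczos downsampling to the
#' target voxel size, patch-referenced white balance, colour enhancement,
#' V-channel brightness transfer, volume stacking, and NIfTI writing. Each
#' stage logs its parameters and per-slice diagnostics; identical inputs
#' and config always produce a byte-identical volume.
#'
#' @param input_dir Directory of numbered `slice_*.png` / `.jpg` images
#'   (at least 2).
#' @param output Output NIfTI path (`.nii` or `.nii.gz`).
#' @param config A [pipeline_config()].
#' @param qc_dir Optional directory for QC artifacts: aligned PNGs,
#'   `fiducials.csv`, `transforms.csv`.
#' @param log_file Optional log file path.
#' @param verbose Print log lines to the console.
#' @return Invisibly, a list with the `volume` ([volume_grid()]), the
#'   per-slice `fiducials`, the alignment `qc` data frame and the output
#'   `path`.
#' @export
run_pipeline <- function(input_dir, output, config = pipeline_config(),
                         qc_dir = NULL, log_file = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "blockface_config"))
  log <- bf_logger(log_file, verbose)
  acq <- config$acquisition

  images <- with_stage("read", NULL,
                       read_stack(input_dir, acq$pixel_size_mm))
  if (length(images) < 2L)
    stop("input stack must contain at least 2 images")
  log("read: %d images from %s (%g mm/px)", length(images), input_dir,
      acq$pixel_size_mm)

  rr <- config_radius_range(config)
  log("detect: circular Hough, radius range [%.1f, %.1f] px", rr[1], rr[2])
  fids <- vector("list", length(images))
  for (i in seq_along(images)) {
    fids[[i]] <- with_stage("detect", i - 1L, detect_fiducials(
      images[[i]], rr, slice_index = i - 1L,
      edge_threshold = config$fiducials$edge_threshold,
      score_floor = config$fiducials$score_floor))
    log("detect: slice %d: %s", i - 1L,
        paste(sprintf("%s (%.2f, %.2f) r=%.0f", fids[[i]]$corner,
                      fids[[i]]$x, fids[[i]]$y, fids[[i]]$radius),
              collapse = "; "))
  }

  log("align: %s fit onto slice 0",
      if (config$alignment$joint) "joint similarity" else
        "magnification + rigid")
  al <- with_stage("align", NULL,
                   align_stack(images, fiducials = fids,
                               joint = config$alignment$joint))
  for (i in seq_len(nrow(al$qc)))
    log("align: slice %d: scale %.5f rot %.3f deg t (%.2f, %.2f) rms %.3f px",
        al$qc$slice_index[i], al$qc$scale[i], al$qc$rotation_deg[i],
        al$qc$tx[i], al$qc$ty[i], al$qc$rms_residual_px[i])

  log("downsample: Lanczos-3 to %g mm", acq$target_voxel_mm)
  small <- lapply(seq_along(al$aligned), function(i)
    with_stage("downsample", i - 1L,
               downsample(al$aligned[[i]], acq$target_voxel_mm)))

  pr <- config$color$patch
  patch <- patch_region(pr$x, pr$y, pr$w, pr$h)
  log("white balance: %d x %d paraffin patch at (%d, %d)",
      pr$w, pr$h, pr$x, pr$y)
  small <- lapply(seq_along(small), function(i)
    with_stage("white_balance", i - 1L, white_balance(small[[i]], patch)))

  log("enhance: saturation factor %.3g", config$color$enhance_factor)
  small <- lapply(seq_along(small), function(i)
    with_stage("enhance", i - 1L,
               enhance_color(small[[i]], config$color$enhance_factor)))

  ref_stats <- if (config$color$brightness_reference == "first") {
    v_channel_stats(small[[1]])
  } else {
    all_stats <- lapply(small, v_channel_stats)
    channel_stats(mean(vapply(all_stats, `[[`, numeric(1), "mean")),
                  mean(vapply(all_stats, `[[`, numeric(1), "sd")),
                  sum(vapply(all_stats, `[[`, integer(1), "n")))
  }
  log("brightness transfer: reference `%s` (V mean %.2f, sd %.2f)",
      config$color$brightness_reference, ref_stats$mean, ref_stats$sd)
  small <- lapply(seq_along(small), function(i)
    with_stage("brightness", i - 1L,
               transfer_brightness(small[[i]], ref_stats)))

  vol <- with_stage("stack", NULL,
                    build_volume(small, acq$slice_spacing_mm))
  log("stack: %d x %d x %d voxels at %g mm isotropic",
      dim(vol$voxels)[1], dim(vol$voxels)[2], dim(vol$voxels)[3],
      vol$voxel_size_mm)

  dir.create(dirname(output), showWarnings = FALSE, recursive = TRUE)
  with_stage("write", NULL, write_nifti(vol, output,
                                        encoding = config$volume$encoding))
  log("write: %s (%s encoding)", output, config$volume$encoding)

  if (!is.null(qc_dir)) {
    dir.create(qc_dir, showWarnings = FALSE, recursive = TRUE)
    fiducials_to_csv(fids, file.path(qc_dir, "fiducials.csv"))
    transforms_to_csv(al$qc, file.path(qc_dir, "transforms.csv"))
    for (i in seq_along(small))
      write_raster(small[[i]],
                   file.path(qc_dir, sprintf("aligned_%04d.png", i - 1L)))
    log("qc: wrote fiducials.csv, transforms.csv and %d aligned PNGs to %s",
        length(small), qc_dir)
  }

  invisible(list(volume = vol, fiducials = fids, qc = al$qc, path = output))
}
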