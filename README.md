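# blockface

Reconstruction of isotropic 3D RGB volumes from serial blockface
photographs of paraffin-embedded specimens.

## The problem

When a large embedded specimen — up to a whole human cerebral hemisphere —
is serially sectioned on a sliding microtome, the thin sections themselves
distort (folds, tears, shear), but the cut face of the block does not.
Photographing the blockface after every k-th cut therefore yields a stack of
images whose geometry is trustworthy, from which a coherent 3D volume can be
reconstructed. When the main cerebral arteries were injected beforehand with
colored media, the reconstructed volume shows their distribution territories
directly in RGB.

Three acquisition artifacts stand between the raw photographs and a usable
volume:

1. **Magnification drift.** The camera is fixed, but each cut moves the
   blockface away from it, so the specimen shrinks slowly across the stack.
2. **Pose jitter.** Vibration during cutting adds small per-image rotations
   and translations.
3. **Exposure and tint variability.** The specimen/paraffin ratio on the
   face changes the reflected light, so exposure and white balance drift
   even under fixed camera settings.

The first two are corrected using four dark circular fiducial markers —
holes drilled at the block corners and filled with black paraffin — present
in every photograph at fixed physical positions:

- marker centers are detected with a gradient-direction **circular Hough
  transform** and refined to subpixel precision;
- the per-image **magnification factor** is the mean ratio of the six
  inter-marker distances relative to the first image;
- the residual **rotation + translation** is the closed-form least-squares
  rigid fit (2D orthogonal Procrustes) of the scale-corrected marker
  correspondences onto the first image, the registration target.

Every image is then resampled into the reference frame (bicubic), Lanczos
(a = 3) downsampled to the target resolution, white-balanced against a
25 × 25 px patch of pure paraffin, color-enhanced, brightness-matched by
transferring the HSV value-channel mean and standard deviation of the
reference, stacked, and written as an RGB NIfTI-1 volume. With 20 µm cuts
photographed every tenth cut (0.2 mm spacing) and in-plane downsampling to
0.2 mm, the volume is isotropic by construction — the builder refuses
anisotropic input rather than silently resampling.

A synthetic blockface generator (`generate_stack()`) emulates the whole
rig — phantom specimen with three colored territories, corner markers,
pinhole magnification drift `d0 / (d0 + i·Δz)`, pose jitter, exposure gain
and white-balance tint — with exact ground truth for every slice, so the
full pipeline is testable without any physical specimen.

## Worked example

Simulate a six-slice session at the scaled 1500 × 1000 px geometry
(150 × 100 mm field, 0.1 mm pixels, 20 µm cuts, photograph every tenth
cut) and reconstruct it:

```r
library(blockface)

cfg <- pipeline_config(seed = 1)
stack_dir <- file.path(tempdir(), "demo-stack")
simulate_to_dir(cfg, stack_dir, n_slices = 6, seed = 1)
res <- run_pipeline(stack_dir, file.path(tempdir(), "hemisphere.nii.gz"),
                    cfg, verbose = FALSE)
print(res$volume)
print(res$qc, digits = 4)
```

```
<blockface_volume> 6 slices x 500 x 750 px RGB, 0.2 mm isotropic
  slice_index scale rotation_deg     tx     ty rms_residual_px
1           0 1.000       0.0000  0.000  0.000         0.00000
2           1 1.000       0.4694  8.962 -9.203         0.01787
3           2 1.001      -0.3207 -8.464 21.363         0.01527
4           3 1.001      -0.5393 -5.563 -2.253         0.01436
5           4 1.002       0.5760 -2.399  6.602         0.01654
6           5 1.002      -0.7391 -1.481  9.380         0.02895
```

Reading the table: `scale` is the recovered magnification correction
(growing as the camera–blockface distance increases slice by slice),
`rotation_deg`/`tx`/`ty` the rigid motion registering each slice onto
slice 0, and `rms_residual_px` the RMS marker mismatch after the fit — a
few hundredths of a pixel here, i.e. the four markers are brought into
almost perfect register. The volume is 750 × 500 × 6 voxels at 0.2 mm
isotropic and opens as a color volume in any RGB-capable NIfTI viewer
(`encoding = "channels"` writes a 4-D fallback for viewers without RGB
support).

A command-line front end with `simulate`, `detect`, `align`,
`reconstruct` and `run` subcommands is installed under
`inst/cli/blockstack.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/blockstack.R", package="blockface"))')" \
  run --out volume.nii.gz --n 10 --seed 1
```

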