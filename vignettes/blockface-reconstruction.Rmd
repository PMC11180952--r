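---
title: "Blockface volume reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blockface volume reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents what the package computes and why it computes it
that way: the imaging model, the estimation procedures, the parameters a
user may want to touch, the numerical conventions, and the choices we made
where the method leaves room for interpretation.

## Imaging model

A fixed camera photographs the face of a paraffin block after every k-th
microtome cut. Writing $\Delta z$ for the spacing between photographed
faces (cut thickness $\times$ k; 0.2 mm for 20 µm cuts and k = 10), the
blockface recedes from the camera by $\Delta z$ per photograph, and under
a pinhole model slice $i$ is imaged at scale

$$s_i = \frac{d_0}{d_0 + i\,\Delta z},$$

with $d_0$ the initial camera–blockface distance. On top of this
deterministic shrink, cutting vibration adds a small per-image rotation
and translation, and the varying specimen/paraffin ratio perturbs exposure
and white balance even under fixed camera settings. Four black-paraffin
fiducial markers drilled near the block corners are the anchors for
undoing the geometric part; a paraffin patch and the first image's
brightness statistics anchor the photometric part.

Coordinates are 0-based pixel centres, origin at the top-left, x
rightward, y downward. A similarity transform maps source to reference
coordinates as $q = s\,R(\theta)\,p + t$; reflections are excluded because
a block cannot flip between cuts.

## Estimation procedures

**Marker detection.** Luma inversion (markers are dark), Sobel gradients,
then a gradient-direction circular Hough vote: each edge pixel votes one
radius along its gradient direction, once per candidate radius, weighted
by gradient magnitude. Peaks are pooled over a 3 × 3 neighbourhood,
thresholded at `score_floor` (votes normalised by circumference), and
thinned by non-maximum suppression at twice the maximum search radius.
Each surviving centre is refined to subpixel precision as the
darkness-weighted centroid of below-threshold pixels inside the circle,
with the threshold picked by Otsu's method over the interior plus a
surrounding annulus. The centroid, not the integer Hough peak, is what
the registration consumes; the method description leaves the question of
subpixel refinement open, and the centroid makes recovery accurate to a
few hundredths of a pixel on synthetic data, so we refine.

**Magnification.** The scale factor of each image is the mean, over the
six marker pairs, of the reference-to-source inter-marker distance ratio.
Whether the original implementation averaged all six pairs or a subset is
not documented; all six is the variance-minimising choice among the
obvious options and is what we use.

**Rigid fit.** With the scale fixed, the rotation and translation
minimising the summed squared corner residuals have the classical closed
form: $\theta = \operatorname{atan2}(\sum p' \times q', \sum p' \cdot q')$
on centred points, translation from the centroids. We deliberately keep
the two-stage structure — scale from distances, then a rigid fit on
scale-corrected points — rather than folding everything into one 4-dof
similarity fit, because the two-stage form is the described procedure; the
joint fit (`estimate_similarity()`, `alignment: joint: true`) is offered
for comparison and agrees on clean points. The RMS corner residual is
attached to every fitted transform and exported in the QC table.

**Registration target.** The first image of the stack. Its own pose
defines the output frame, so in the synthetic generator slice 0 is
rendered at nominal pose (unit scale, no jitter, neutral exposure): the
ground-truth frame and the reconstruction frame then coincide, which makes
end-to-end comparisons direct instead of requiring a frame-alignment step
in every test.

## Processing order and photometric steps

Stages run in a fixed order: detect → magnify + register (at full input
resolution) → resample → Lanczos downsample → white balance → colour
enhancement → brightness transfer → stack → write. Alignment precedes
every photometric step so that patch coordinates can be specified once in
the aligned frame ("the same area" stays paraffin despite camera drift),
and downsampling precedes white balance, matching the described
preprocessing sequence.

**White balance.** Per-channel gains $g_c = L / m_c$, with $m_c$ the patch
channel means and $L$ their average. The cited "ground-truth" white
balance treats the patch as true white but does not print its target
constant; normalising to the patch's own mean luminance (rather than to
255) neutralises the patch without blowing out the image, and makes the
operation idempotent up to quantization. A patch whose channel standard
deviation exceeds a ceiling (default 12 intensity units) triggers a
warning — it probably covers more than paraffin.

**Colour enhancement.** `out = gray + factor · (in − gray)` about the
per-pixel BT.601 luma. The enhancement factor is not documented; the
default 1.3 is a mild, purely cosmetic boost and is configurable.

**Brightness transfer.** HSV value channel only (hexcone model on
[0, 255], $V = \max(R,G,B)$): $V' = (V - \mu_{src})\,\sigma_{ref}/
\sigma_{src} + \mu_{ref}$, hue and saturation untouched. The reference is
the first image's statistics by default (consistent with it being the
registration target); `brightness_reference: global` uses the stack-wide
mean statistics instead. Source statistics are computed on the whole
frame: a specimen mask would track the specimen/paraffin ratio better but
needs a segmentation the method does not define.

## Volume assembly

Isotropy is enforced, not produced: `build_volume()` errors unless the
in-plane pixel size equals the slice spacing within 1e-9 mm, telling the
user to adjust the downsampling target or photograph interval. With the
full-resolution geometry (0.025 mm pixels, 8× downsampling, 0.2 mm
spacing) and with the scaled default (0.1 mm pixels, 2×) the equality
holds exactly.

Orientation: slice 0 first, slice index increasing along +z of a
right-handed frame, in-plane axes following image x/y; the anatomical
orientation of a real block depends on how it was mounted and is not
recoverable from the images, so the affine encodes only the voxel scaling
and this axis convention. Voxels are written as NIfTI RGB24 by default;
`encoding = "channels"` writes a 4-D uint8 fallback for viewers without
RGB support. Both round-trip 8-bit data losslessly.

## Synthetic generator

The generator emulates what the correction pipeline must undo, with exact
per-slice ground truth (transform, exposure gain, tint, marker centres):

* elliptical specimen with three angular-sector territories in distinct
  colours (blue/red/green, as injected arterial labeling media), semi-axes
  slowly modulated along the stack so consecutive faces differ;
* four dark corner markers at fixed physical positions (default 10 mm
  inset, 2.5 mm radius), validated to stay outside the specimen and inside
  the frame;
* pinhole magnification drift, default $d_0$ = 500 mm — with 0.2 mm per
  photograph this shrinks the image by about 0.04 % per slice, the right
  order of magnitude for a close-range macro rig;
* per-slice jitter: rotation U(−1°, 1°), translation U(−20, 20) px —
  "slight camera movements, minimal displacement" — exposure gain
  U(0.9, 1.1) and per-channel tint U(0.95, 1.05). The exposure range is a
  modelling choice: the observed differences are described only as
  "slight", so ±10 % is deliberately generous; a pipeline that equalises
  it will equalise less.

Rasterization is anti-aliased (4 × 4 supersampling of boundary-band
pixels), which is what makes subpixel centre recovery meaningful, and
quantized to 8 bits with round-half-up and clipping at 255. The default
frame is 1500 × 1000 px over the same 150 × 100 mm field (0.1 mm pixels)
so a full synthetic study runs in minutes on one core; the full
6000 × 4000 geometry is available through `acquisition_params()`.

What the phantom does **not** emulate: tissue texture, specular
reflections, depth-of-field, lens distortion, marker damage or partial
occlusion, and non-rigid block deformation. Passing tests on synthetic
stacks therefore validate the geometry/photometry corrections under the
modelled disturbances — not robustness to real-world optical artifacts,
which needs real data.

## Numerical conventions and degenerate inputs

* 8-bit quantization everywhere is round-half-up with clipping; identity
  operations (`enhance_color(·, 1)`, identity resampling, identity-target
  downsampling) are exact byte-identities by construction.
* Alignment resampling is bicubic (Keys, a = −0.5); integer translations
  are exact. Out-of-frame pixels are filled with the median colour of a
  10 px border ring of the reference image (approximately paraffin),
  avoiding dark frames in the volume. Downsampling uses Lanczos-3 with the
  kernel support scaled by the downsampling factor and border weights
  renormalised; constants are fixed points.
* Hough tie-breaks: equal accumulator peaks are ordered by lower y then
  x — determinism over elegance.
* Degenerate inputs fail loudly with classed errors: fewer than four
  peaks (`blockface_detection_error`, carrying how many were found), two
  detections in one quadrant, markers too close to the border, collinear
  or coincident marker geometry, sub-pixel inter-marker distances,
  constant images in brightness transfer, black white-balance patches,
  mixed slice dimensions, and anisotropic voxel requests.
* The acceptance-grade checks in the test suite use a 20-slice stack at
  the default scaled frame for transform recovery and a 10-slice stack for
  the end-to-end reconstruction and territory-recovery checks; these sizes
  keep a full run on one core in the minutes range while leaving every
  per-slice quantity (4 markers, 6 distance pairs) identical to a
  full-length session.

## Known limitations

* The magnification model assumes a pinhole camera and a flat, parallel
  blockface; angulation-induced perspective is not modelled (the rig is
  levelled to avoid it).
* Registration is strictly similarity-based on four points; it cannot
  absorb non-rigid block deformation, and a damaged or occluded marker
  aborts the slice rather than falling back to three-point estimation.
* Brightness transfer matches first and second moments only, and only on
  V; strong clipping (more than a percent of pixels) degrades the match.
* JPEG input is supported for reading, but all intermediates are written
  as lossless PNG; quantization noise from aggressive JPEG compression of
  the input is not modelled by the generator.
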