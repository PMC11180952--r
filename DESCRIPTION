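Package: blockface
Title: Blockface Photograph Registration and 3D Volume Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs isotropic 3D RGB volumes from serial photographs of
    a paraffin block face. Serial sectioning of large embedded specimens with
    corner fiducial markers (black-paraffin filled drill holes) yields an
    ordered stack of photographs in which the specimen slowly shrinks (the
    camera-to-blockface distance grows as the block is cut down) and drifts by
    small rotations and translations. The package detects the four dark
    circular fiducial markers with a gradient-weighted circular Hough
    transform, corrects per-image magnification from inter-marker distances,
    rigidly coregisters every image onto the first, normalizes white balance
    and brightness across the stack, downsamples with a Lanczos filter, and
    assembles the result into an isotropic RGB NIfTI volume. A synthetic
    blockface generator with full ground truth (per-slice transforms, exposure
    gains, white-balance tints, marker centers) makes the whole pipeline
    testable without any physical specimen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    RNifti,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
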