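Package: parstain
Title: Virtual Hematoxylin-Eosin Staining for Multi-Contrast
    Photoacoustic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for computational hematoxylin-eosin (H&E)
    colorization of label-free, multi-contrast photoacoustic remote sensing
    images. Covers raster image formation from per-pulse scan records,
    landmark-based thin-plate-spline co-registration of brightfield H&E onto
    the photoacoustic frame, percentile contrast stretching and color
    reversal, deterministic overlapping tiling with raised-cosine stitching,
    a conditional adversarial colorization network (U-Net generator and
    patch-level discriminator trained with a binary cross-entropy plus L1
    objective), and patchwise SSIM/RMSE evaluation in CIELAB. A seedable
    synthetic tissue-phantom generator provides fully ground-truthed inputs
    so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
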