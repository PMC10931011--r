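Package: fluorocal
Title: Self-Calibrating Bundle Adjustment for Single-Plane Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric calibration of image-intensifier fluoroscopy systems by
    free-network self-calibrating bundle adjustment. Models the collinearity
    condition with radial, decentering, affinity, sigmoid (spiral) and local
    distortion terms, estimates interior and exterior orientation together with
    object-space bead coordinates by weighted nonlinear least squares under
    inner-constraint datum definition, and selects significant distortion terms
    greedily. Includes a synthetic bead-phantom image network generator,
    sub-pixel bead centroid detection from rasters, per-pixel distortion-field
    image correction, fluoroscopy video-volume utilities, and accuracy
    assessment via image-residual RMS and held-out 3D reconstruction of
    inter-bead distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
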