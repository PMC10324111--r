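Package: stemspot
Title: Stem Diameter Measurement from Laser-Spot Referenced Panchromatic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated stem-diameter (SD) measurement for forest inventory from
    single panchromatic images carrying a laser spot of known physical size.
    Implements the spot detection algorithm (morphological top-hat enhancement,
    centre-of-frame component selection, crop-invariant coordinate correction,
    gradient-ring edge extraction and least-squares circle fitting), trunk
    segmentation (a deterministic thresholding baseline and an attention-augmented
    nested U-net with spot-conditioned local crops and depth-weighted deep
    supervision, trained with Adam on a built-in reverse-mode tape), and the
    scale-reference geometry converting pixel widths to centimetres. A seeded
    synthetic scene generator with full ground truth makes every stage testable
    without field data, and saliency/error evaluation metrics (S-measure,
    E-measure, weighted F-measure, RE/MAE/MSE/RMSE/R2) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
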