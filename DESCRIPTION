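Package: insectseg
Title: Instance Segmentation of Insect Anatomy from Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects, classifies and pixel-extracts insect anatomical
    components (thorax, abdomen, wings, legs) from RGB images with an
    anchor-based instance segmentation network: a residual backbone with a
    feature pyramid, a region proposal stage, and parallel classification,
    box-tightening and masking heads trained with categorical cross-entropy,
    focal and smooth-L1 losses on CPU.  Includes a synthetic insect image
    generator with exact polygon ground truth (reproducing the extreme
    background-versus-leg pixel imbalance of thin legs), VGG Image Annotator
    (VIA) JSON input/output with polygon rasterization, and precision /
    recall / IoU / mean-average-precision evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
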