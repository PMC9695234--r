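Package: usseg
Title: Liver Lesion Segmentation for B-Mode Ultrasound Examinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for semantic segmentation of liver lesions
    in B-mode ultrasound video examinations: frame extraction and device-specific
    cropping, rasterization of expert polygon annotations into binary masks, a
    compact U-Net encoder-decoder trained with the focal Tversky loss family
    under two parameter regimes, imbalance-aware evaluation metrics (IoU, Dice,
    recall, precision, pixel-level ROC AUC), and an inference timing harness.
    A synthetic speckle-textured B-mode phantom generator provides reproducible
    examinations with exact ground-truth masks so every stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mgcv,
    optparse
Config/testthat/edition: 3
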