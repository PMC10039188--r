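Package: wristseg
Title: Segmentation-Based Detection of Distal Radius Fractures in Wrist Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patch-based semantic-segmentation pipeline for detecting distal
    radius fractures in two-view wrist radiograph examinations. Provides a
    synthetic radiograph simulator with pixel-level fracture masks, deterministic
    preprocessing (physical resampling, contrast-limited adaptive histogram
    equalization, intensity normalization), exact size arithmetic for
    valid-padding U-Net architectures with tiled inference, stitching and
    shift-and-average test-time ensembling, a from-scratch trainable U-Net with
    an auxiliary patch-classification head and two-phase training schedule, and
    a complete diagnostic-evaluation layer (confusion matrices, sensitivity,
    specificity, predictive values, likelihood ratios, post-test probabilities,
    bootstrap ROC/AUC, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
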