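Package: pleospectrum
Title: Continuous-Spectrum Nuclear Pleomorphism Scoring for Breast Histology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automated nuclear pleomorphism grading of breast-cancer
    histology as a continuous severity spectrum rather than the traditional
    three discrete categories. The package provides a seeded synthetic H&E
    image generator with full nuclear ground truth, an epithelial cell
    detector with a labeled point-detection contract, nuclear density maps and
    density-guided patch sampling, a trainable dense-block convolutional
    regressor with smooth-L1 loss and Grad-CAM saliency, overlapping-tile
    whole-slide inference with per-block average pooling and heatmap
    rendering, quantization of continuous scores into categories, and a full
    observer-agreement harness (panel simulation, average-pooled reference
    scores, confidence-weighted majority voting, quadratic weighted kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Classification, Regression, CellBasedAssays
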