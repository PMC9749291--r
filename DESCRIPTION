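Package: ctgmorse
Title: Fetal Distress Detection from Cardiotocogram Scalograms with
    Generalized Morse Wavelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for computer-aided detection of fetal
    distress from cardiotocogram (CTG) fetal-heart-rate (FHR) recordings
    sampled at 4 Hz. Provides rule-based artifact removal (long-gap
    deletion, edge trimming, linear interpolation of outliers and short
    dropouts, cubic-spline spike repair), labor-stage segmentation,
    minority-class window-slicing augmentation, a generalized Morse
    wavelet continuous wavelet transform with scalogram image rendering,
    stratified data splitting, a pluggable transfer-learning image
    classifier with an Adam-trained softmax head, and confusion-matrix
    evaluation (accuracy, sensitivity, specificity). Includes a synthetic
    FHR simulator with a defect ledger so every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
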