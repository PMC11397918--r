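Package: rfstage
Title: Liver Fibrosis Staging from Ultrasound Radiofrequency Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step quantitative-ultrasound pipeline for liver fibrosis
    staging from raw backscattered radiofrequency (RF) frames. B-mode images
    are reconstructed by Hilbert envelope detection and logarithmic
    compression, liver regions of interest are segmented by 2D
    encoder-decoder convolutional networks (U-Net and Attention U-Net), and
    binary fibrosis-stage dichotomies (>=F1 ... >=F4) are classified by a 1D
    convolutional network applied to per-scan-line frequency spectra
    (amplitude, phase, power) of the ROI-masked signals, with whole-frame
    majority voting. Includes a synthetic RF phantom simulator with
    stage-dependent scatterer statistics and ground-truth masks so every
    stage is trainable and testable without clinical data, a compact CNN
    engine (im2col + BLAS via RcppArmadillo, manual backpropagation, Adam),
    sliding-gate/sliding-window spectrum augmentation with class balancing,
    and segmentation/classification metrics including ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
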