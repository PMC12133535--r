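Package: ultraseg
Title: Ultrasound Lesion Segmentation with Residual ECA-UNet++ Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automatic segmentation of lesions in B-mode
    ultrasound images using a nested U-Net (UNet++) decoder over a
    ResNet34-style residual encoder with efficient channel attention
    (ECA), trained with deep supervision. Includes a deterministic
    synthetic ultrasound phantom generator (speckle noise, acoustic
    shadows, fuzzy low-contrast boundaries) so the full pipeline is
    testable without clinical data; a paired-PNG dataset loader with
    mask-consistent augmentation; exact segmentation metrics (Dice,
    mean IoU, accuracy, sensitivity, specificity, Hausdorff distance,
    pooled pixelwise ROC/AUC); the complete training protocol (AdamW,
    cosine annealing, early stopping on validation Dice); and a model
    compression pipeline with L1-norm structured channel pruning and
    post-training INT8 quantization. The convolutional network engine
    (forward, reverse-mode gradients, optimizer) is implemented in
    R and C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
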