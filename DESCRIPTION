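Package: cambnet
Title: Cross-Attention Multi-Branch CNN for Breast DCE-MRI Molecular
    Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements CAMBNET, a compact three-branch convolutional
    network with a cross-attention module for classifying luminal versus
    non-luminal breast-cancer molecular subtype from contoured DCE-MRI
    tumor patches. Provides the full pipeline around the model: a
    synthetic lesion-phantom cohort generator with per-patient metadata,
    contour-driven ROI extraction (bounding box with margin, bilinear
    resize, normalization), patient-wise stratified splitting and k-fold
    planning, an RMSprop training loop with learning-rate decay, L2 and
    max-norm regularization and best-on-validation checkpointing,
    confusion-matrix metrics and rank-based ROC AUC, subgroup evaluation
    stratified by age at menarche and tumor size, and Grad-CAM
    class-activation maps with a mask-based localization score. The
    network forward and backward passes are implemented in the package
    with RcppArmadillo convolution kernels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'cambnet-package.R'
    'preprocess.R'
    'synthetic.R'
    'io.R'
    'nn-ops.R'
    'model.R'
    'explain.R'
    'evaluation.R'
    'training.R'
    'config.R'
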