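Package: DenseVessel
Title: Patch-Based Retinal Vessel Segmentation with a Dense U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Patch-based segmentation of retinal blood vessels in fundus
    photographs. Training patches are sampled at random positions whose
    centers lie inside the field-of-view (FOV) mask; a densely connected
    convolutional U-Net (dense blocks with a fixed growth rate, transition
    down/up layers and skip concatenations) is trained with a soft dice
    loss by stochastic gradient descent; test images are tiled with
    overlapping patches and the per-pixel probabilities are averaged back
    into a full-image vessel probability map. Includes elastic
    displacement-field augmentation, FOV-masked sensitivity/specificity/
    accuracy/AUC evaluation, a synthetic vascular-phantom generator for
    self-contained experiments, and a command-line pipeline
    (simulate/train/predict/evaluate) for DRIVE-style directories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'DenseVessel-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'augmentation.R'
    'evaluation.R'
    'io.R'
    'network.R'
    'patches.R'
    'phantom.R'
    'pipeline.R'
    'preprocessing.R'
    'reconstruction.R'
    'training.R'
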