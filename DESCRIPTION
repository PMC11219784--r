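Package: lmbisnet
Title: Lightweight Multipath Bidirectional-Skip Network for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates LMBiS-Net, a lightweight (under 0.172
    million parameter) encoder-decoder convolutional network with multipath
    feature-extraction blocks and bidirectional skip connections for segmenting
    blood vessels in fundus photographs. Includes fundus image/mask I/O
    (PNG, TIFF, JPEG, PPM), the 38-fold rotation/contrast augmentation policy,
    dice-loss training with Adam, learning-rate halving on plateau and early
    stopping, per-image and dataset-level evaluation metrics (sensitivity,
    specificity, accuracy, F1, closed-form AUC), a seeded synthetic fundus
    generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
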