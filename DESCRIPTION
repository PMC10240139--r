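Package: mdunet
Title: Semi-Supervised Multi-Decoder U-Net for Retinal Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pixel-level segmentation of diabetic-retinopathy lesions
    (microaneurysms, hemorrhages, hard and soft exudates) from color fundus
    photographs with a single-encoder, multi-decoder U-Net trained in two
    phases: unsupervised image reconstruction on an unlabeled pool, then
    supervised multi-task training in which one lesion is the primary task
    and the remaining lesions act as auxiliary regularizers.  Ships the full
    pipeline: dataset manifests and deterministic splits, fundus
    preprocessing (border crop, histogram equalization, bicubic resize),
    a synthetic fundus generator with exact ground-truth masks, soft dice
    and reconstruction losses, SGD training, and a segmentation evaluation
    suite (dice, AUC-ROC, AUC-PR, MAE, sensitivity).  The network and its
    backpropagation are implemented natively on 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    EBImage,
    optparse
Config/testthat/edition: 3
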