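Package: rpsnet
Title: Dense Encoder-Decoder Segmentation of Retinal Pigment Signs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and quantification of retinitis-pigmentosa pigment
    signs in color fundus images. Implements a densely connected
    encoder-decoder semantic-segmentation network (in-block and
    encoder-to-decoder depth concatenation, 1x1 bottlenecks, max-unpooling
    driven by recorded pooling indices), a four-stage flip/translation
    augmentation cascade, median-frequency class balancing with weighted
    per-pixel cross-entropy and Adam training, patient-wise k-fold
    cross-validation, pixel-level ROC/EER/AUC evaluation with bilinear
    upscaling of predictions, and connected-component analytics (count,
    size, location, inter-deposit distances) of the segmented pigment
    deposits. Includes a synthetic fundus-image generator with exact
    ground-truth masks for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
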