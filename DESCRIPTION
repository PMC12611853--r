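Package: noduleseg
Title: Lung-Nodule Semantic Segmentation with Multi-Scale UNets and an
    Attention-Aggregating Feature Pyramid Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semantic segmentation of pulmonary nodules on 2D CT
    slices. Provides a CT preprocessing chain (standardization, median and
    Perona-Malik anisotropic-diffusion filtering, K-means lung-candidate
    thresholding, morphological opening, connected-component lung-region
    selection and ROI extraction), reader-consensus rasterization of nodule
    contour annotations, and three trainable encoder-decoder segmentation
    networks: a multi-scale UNet (parallel 3x3/7x7 kernels), a UNet with
    asymmetric convolution blocks, multi-scale skip connections and channel
    attention, and a ResNet-34 feature pyramid network refined by a
    linear-time (first-order Taylor, L2-normalized) attention aggregation
    module. Includes a BCE-Dice training objective, overlap metrics
    (precision, recall, accuracy, Dice, IoU), a reproducible synthetic
    thorax-phantom generator so the full pipeline is testable without
    external data, and a command-line interface. Networks run on a compact
    built-in reverse-mode automatic-differentiation core with C++
    convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    png,
    RNifti,
    jsonlite,
    xml2,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
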