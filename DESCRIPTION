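Package: pathogait
Title: Pathological Gait Recognition from Side-View Silhouettes with Fused
    Energy Images and Parallel Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising pathological gait (festinating, scissor,
    hemiparetic, shuffling, normal) from side-view binary silhouette
    sequences. Implements automatic gait-cycle segmentation from the
    width-to-height ratio of the silhouette bounding box, the classical
    gait energy templates (GEI, GEnI, AEI), fusion of the three templates
    into a fused energy image (FEI) with weights optimised by batch
    gradient descent, a parallel-topology convolutional block attention
    module built on depthwise-separable convolutions, and a lightweight
    dual-branch MobileNetV2-style classifier with a depthwise-separable
    classification head, trained in a transfer-learning regime (frozen
    backbone, trainable attention and head). A seeded parametric
    silhouette-walker generator with ground-truth gait periods makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
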