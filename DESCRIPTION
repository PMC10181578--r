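Package: cryolo
Title: Flowering-Stage Detection with a Coordinate-Attention RepVGG YOLOv5s
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CR-YOLOv5s single-stage detector for
    flowering-stage phenotyping (chrysanthemum buds versus open blooms):
    coordinate-attention and RepVGG building blocks, the structural
    reparameterization that folds the trained multi-branch network into a
    single-path inference network with verified output equivalence,
    CPU training via a small built-in reverse-mode autodiff engine,
    PR-curve/mAP detection metrics, YOLO-format dataset handling with
    letterbox and mosaic augmentation, and a seeded synthetic
    chrysanthemum-scene generator so the whole pipeline is testable
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jpeg,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
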