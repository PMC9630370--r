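Package: vbcascade
Title: Coarse-to-Fine Cascade Segmentation of 3D Medical Volumes with VB-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, CPU-only implementation of a two-stage
    (coarse-to-fine) volumetric segmentation framework for radiotherapy
    organ-at-risk and target-volume delineation. Provides geometric volume
    types with NIfTI-1 input/output, spacing-based resampling and CT/MRI
    intensity normalization; a deterministic synthetic CT-like phantom
    generator; a small V-Net-style encoder-decoder ("VB-Net") with bottleneck
    residual blocks and an optional adaptive input module, built on hand-coded
    3D convolutions with exact backpropagation; a multi-dimensional adaptive
    Dice loss family (3D Dice, per-slice 2D Dice with adaptive weights,
    boundary Dice, focal loss); patch-based training with global/mask
    sampling, augmentation, Adam and early stopping; cascade inference with
    bounding-box localization, sliding-window prediction, attention channels
    and connected-component post-processing; and Dice-based evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
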