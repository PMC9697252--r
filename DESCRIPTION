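Package: hierfusion
Title: Multi-Perspective Hierarchical Deep-Fusion Learning for Nodule
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical decision-level fusion for 3D nodule versus
    non-nodule classification. Volumes of interest are sliced along the
    transverse, coronal and sagittal perspectives; a compact convolutional
    network scores each slice, a perspective module fuses the slice scores
    of each view, and a volume module fuses the three perspective scores
    into the final decision, with every level trained separately in a
    modular fashion. Optional feature-image front ends (Laplacian of
    Gaussian, Gabor, bilateral and trilateral filters) and a top-level
    multi-feature fusion stage are included, together with a synthetic
    CT-phantom generator with multi-reader annotations, consensus and
    volume-of-interest extraction, and level-wise evaluation (accuracy,
    AUC, F1, sensitivity, specificity, false positives per scan).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
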