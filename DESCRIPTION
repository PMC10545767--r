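Package: cytomil
Title: Multiple-Instance Learning with Contrastive Instance Disentangling
    for Cytology Slide Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of cytology whole-slide images
    under the multiple-instance learning (MIL) paradigm. Implements a
    contrastive instance-disentangling bag classifier (MIPCL) in which a
    sigmoid disentangler splits each encoded tile feature into foreground and
    background parts contrasted by an InfoNCE loss, Grad-CAM over the
    activated instances yields per-tile class probabilities, and instances
    above a probability threshold are pooled for bag-level classification.
    Ships attention-based MIL (ABMIL) and clustering-constrained attention
    MIL (CLAM) baselines, an HSV-mask tessellation front-end that turns slide
    images into tile feature bags, HDF5 bag persistence, a stratified 10-fold
    cross-validation harness with class-weighted bag sampling and paired
    statistical model comparison, a synthetic bag and smear simulator for
    end-to-end testing, and tile-level explainability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    rhdf5,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    jsonlite
Config/testthat/edition: 3
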