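Package: condylecast
Title: Ray-Cast Joint-Gap Features and Automated Condylar Seating Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the temporomandibular joint space from paired
    condyle/fossa segmentation masks by casting rays from the condyle
    centroid along a hemisphere of directions and measuring the
    condyle-to-fossa gap in millimeters along each ray, then classifies
    each joint as correctly or incorrectly seated with a small
    feed-forward neural network trained under a cyclic learning rate.
    Includes multi-reader majority-rule label fusion, mirroring and
    rigid-perturbation augmentation, stratified k-fold cross-validation
    with confusion-matrix metrics and ROC/AUC, and an analytic
    sphere-phantom generator so every pipeline stage is testable
    against closed-form geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
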