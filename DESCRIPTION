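Package: pancmorph
Title: Pancreas Morphometrics and Multimodal Prediction of Beta-Cell Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pancreas morphology from 3D binary masks
    (volume, surface area, bounding box, centroid, principal axis lengths,
    convex volume, solidity, extent, equivalent diameter), computing PET
    uptake measures (SUV, spleen-referenced SUVR-1, aggregate binding), and
    relating them to beta-cell functional outcomes with a bootstrap LASSO
    stability-selection procedure inside nested cross-validation. Includes a
    synthetic cohort generator with known sparse ground truth so every stage
    of the analysis is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
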