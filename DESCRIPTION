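Package: hyperreg
Title: Hypernetwork-Amortized Deformable Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learning-based deformable image registration in which a small
    hypernetwork maps registration loss hyperparameters (regularization
    weight, semi-supervision weight, similarity-metric settings) to the full
    weight vector of a U-Net registration network. A single trained model
    therefore spans the whole hyperparameter landscape, enabling dense
    test-time sweeps and gradient-based hyperparameter tuning against a
    validation metric without retraining. Includes diffeomorphic stationary
    velocity field integration by scaling and squaring, differentiable
    similarity losses (noise-scaled MSE, local normalized cross-correlation,
    soft-histogram mutual information, soft Dice), evaluation metrics (Dice,
    95th-percentile surface distance, Jacobian-determinant statistics), a
    synthetic pair generator with known ground-truth deformations, and NIfTI
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
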