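Package: attsvm
Title: Active Transfer Transductive Support Vector Machines for
    Inter-Helical Residue Contact Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts inter-helical residue-residue contacts in
    alpha-helical transmembrane proteins from co-evolutionary sequence
    features when structure-derived atomic features are available for
    the training examples only.  Implements a transductive support
    vector machine whose unlabeled test examples are augmented with
    class-conditional atomic feature means and iteratively refined by
    k-nearest-neighbour imputation during label switching, plus two
    overfitting controls: validation-peak early stopping and delayed
    margin-based active learning.  Includes the feature-assembly
    pipeline (direct-coupling-analysis score windows, atomic pair
    geometry from PDB structures, predictive-power-ranked principal
    components, heavy-atom contact labeling), a calibrated synthetic
    benchmark generator with a closed-form Bayes reference, and
    evaluation utilities (precision, recall, F1, ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    optparse,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
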