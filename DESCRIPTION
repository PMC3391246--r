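Package: cbfs
Title: Clearness-Based Feature Selection for Labeled Feature Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Filter feature selection for high-dimensional labeled data such
    as microarray gene expression matrices. Implements the CScore clearness
    statistic (the fraction of samples assigned to their own class centroid
    by one-dimensional nearest-centroid clustering), an R-value congestion
    score based on nearest-neighbor class overlap, and the CBFS intersection
    and exact rank-combination algorithms that merge the two rankings.
    Reference implementations of the FSDD distance-discriminant criterion and
    ReliefF feature weighting are included for comparison, together with an
    evaluation harness (stratified k-fold cross-validated KNN/SVM accuracy
    and per-feature Mann-Whitney AUC) and a synthetic-data generator with
    controlled class separability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
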