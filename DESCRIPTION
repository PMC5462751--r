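Package: smurfrank
Title: Hyper-Ensembles of SMOTE-Undersampled Random Forests for
    Imbalanced Variant Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores rare deleterious non-coding variants under extreme
    class imbalance with a hyper-ensemble of random forests: negatives
    are partitioned, each partition is balanced by SMOTE oversampling of
    the positives plus undersampling of the negatives, one probabilistic
    forest is trained per partition, and predictions are averaged.
    Includes genomics-aware cross-validation (cytogenetic-band folds,
    merged genomic-window and TAD folds, progressive negative
    subsampling), ranking metrics suited to heavy imbalance (average
    precision, AUROC, precision/recall/F curves, sensitivity versus
    top-ranked quantile), chromatin-effect feature transforms
    (diff/log-fold of allele probabilities), and a synthetic-data
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
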