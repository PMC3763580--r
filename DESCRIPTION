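Package: cytosel
Title: Cytokine Identification from Protein Sequences via CTD Features
    and a Clustering-Based Selective Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cytokines from primary amino-acid sequences.
    Extracts composition/transition/distribution (CTD) features over
    three-group partitions of the amino-acid alphabet for eight
    physicochemical properties (a 120-dimensional distribution core and
    the full 188-dimensional set), rebalances extremely imbalanced
    training sets with a hybrid of SMOTE minority oversampling and
    K-means cluster undersampling of the majority class, and classifies
    with a selective ensemble that clusters base learners by their
    correctness patterns and assembles a voting committee by circulating
    forward selection. Evaluation reports sensitivity, specificity,
    their geometric mean, and accuracy under stratified
    cross-validation, with a synthetic-sequence generator for
    self-contained experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    optparse,
    ranger,
    rpart,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
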