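Package: DisulfideDesign
Title: Neural-Network Prediction of Disulfide Bond Engineering Sites from Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting residue pairs suitable for engineered
    disulfide bonds by cysteine mutation. Builds labelled residue-pair
    datasets from protein structures (positives from SSBOND records,
    negatives from the nearest crossing pair of sequence neighbours),
    featurizes each pair as the 45 unique pairwise distances between the
    ten backbone and beta-carbon atoms, trains a small fully connected
    neural network classifier, and enumerates, prescreens and ranks
    candidate cysteine-mutation pairs in a target structure. Includes
    ROC/AUC and rank-based evaluation, average distance maps,
    random-forest feature-relevance analysis, and a geometry-aware
    synthetic structure generator for reproducible benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
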