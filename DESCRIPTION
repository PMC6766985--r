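Package: GridTox
Title: Multi-Channel 2D Molecular Grid Featurization and Convolutional
    Toxicity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Featurizes small molecules as six-channel two-dimensional
    property grids (van der Waals potentials over hydrophobicity,
    metallicity, excluded-volume and ionization channels, plus a 12-10
    hydrogen-bond potential channel) and classifies per-endpoint binary
    toxicity with a small convolutional neural network. Includes molecule
    standardization and InChIKey-based deduplication, SMOTE oversampling
    and class weighting for imbalanced endpoints, ROC/AUC evaluation,
    leave-one-channel-out ablation and grid-resolution sweeps, and seeded
    synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, Classification, FeatureExtraction
RoxygenNote: 7.3.3
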