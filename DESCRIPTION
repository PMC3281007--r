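Package: cpsite
Title: Circular Permutation Site Viability Prediction from Protein Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts which positions in a protein chain can serve as viable
    circular permutation sites. Computes per-residue sequence and secondary
    structure propensity scores via permutation-test weighted enrichment,
    tertiary packing and flexibility descriptors (relative solvent
    accessibility, residue depth, contact numbers, closeness centrality,
    Gaussian network model fluctuations, and farness from the buried or
    hydrophobic core), and combines them with a hierarchical feature
    integration procedure and an ensemble of probability-scoring classifiers
    (neural network, random forest with out-of-bag tree selection, and a
    radial-basis kernel classifier). Includes ROC/MCC/PPF evaluation
    utilities and a synthetic structure generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    rpart,
    e1071,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
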