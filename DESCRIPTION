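Package: iseScreen
Title: Iterative Stochastic Elimination Models for Ligand- and
    Structure-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns ensembles of physico-chemical descriptor-range filters
    by iterative stochastic elimination (ISE) to discriminate bioactive
    molecules from presumed inactives, ranks screening libraries by a
    molecular bioactivity index (MBI), and evaluates models by balanced
    Matthews correlation and enrichment factors. Includes training-set
    curation (FP2 fingerprints, Tanimoto diversity pruning,
    applicability-domain sampling of presumed inactives), consensus
    geometric filtering of docking poses against reference receptor
    structures, and synthetic data generators for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment,
    ChemmineR,
    ChemmineOB,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Cheminformatics, Classification, StructuralPrediction
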