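Package: titrADT
Title: Titration Panel Optimization for CITE-seq Antibody-Derived Tags
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for optimizing a CITE-seq antibody (ADT) staining panel
    from a multi-concentration titration experiment. Implements hashtag-oligo
    (HTO) demultiplexing with fraction thresholds, RNA-based quality-control
    filtering, centered log-ratio (CLR) normalization of ADT counts,
    sequencing read-load diagnostics, gradient-boosting (gain) ranking of
    markers by cluster-discriminative value, isotype-referenced dose-response
    profiling, and a decision tree that nominates a keep/exclude/adjust action
    and an optimal working concentration per antibody. Also provides
    cross-batch marker-consistency statistics (k-sample Anderson-Darling,
    binned 1-D Earth Mover's Distance, rank-quantile alignment), per-cluster
    differential ADT abundance via an empirical-Bayes moderated t-test with
    FDR correction, and a synthetic titration-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
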