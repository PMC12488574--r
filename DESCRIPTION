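Package: stageSalience
Title: Stage-Salient Biomarker Mining and Cascade Classification for
    Breast Cancer Heterogeneity
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stage-encoded differential-expression mining for breast
    cancer cohorts: two-level (stage-vs-control and inter-stage) contrast
    protocol yielding stage-salient, monotonic and contra-regulated gene
    calls; consensus feature selection (Boruta-style shadow features and
    cross-validated recursive feature elimination); nested model selection
    over six classifier families with SMOTE class balancing; a cascade
    classifier with per-level confidence readout; and late integration of
    miRNA and DNA-methylation layers through direction and temporal
    concordance rules. A multi-layer synthetic cohort generator with
    planted ground truth makes every stage of the pipeline testable by
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    mclust,
    ranger,
    e1071,
    nnet,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
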