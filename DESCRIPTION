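Package: chemosig
Title: Chemotherapy-Resistance Gene Signatures from In Vitro Panels and
    Patient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for deriving prognostic gene-expression classifiers
    from in vitro drug-response panels. Fits four-parameter log-logistic
    dose-response curves to viability data and extracts IC50 values,
    screens genes by Spearman correlation of expression with IC50 across
    multiple datasets with co-directional intersection, grows logistic
    regression gene signatures by a significance-gated forward beam
    search with repeated cross-validation pruning, and evaluates the
    resulting classifiers against patient survival with Kaplan-Meier,
    log-rank and multivariate Cox proportional-hazards analyses.
    Includes seeded synthetic-data generators that emulate multi-dataset
    in vitro panels with planted IC50-correlated genes and patient
    cohorts with planted prognostic signatures under right-censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    S4Vectors,
    DESeq2,
    edgeR,
    survival,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
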