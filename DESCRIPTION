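Package: cohorttopics
Title: Temporal Topic Modelling of Closed-Cohort Clinical Note Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating and comparing temporal topic models on
    timestamped clinical note corpora from closed cohorts. Implements
    corpus preprocessing into sparse document-term matrices at the note or
    patient-quarter level, nonnegative matrix factorization by Lee-Seung
    multiplicative updates, latent Dirichlet allocation by collapsed Gibbs
    sampling, time-stratified topical-prevalence series with bootstrap
    uncertainty bands and Ward clustering of topic trajectories, and a
    model-comparison battery (topic diversity, UMass/UCI/NPMI coherence,
    Jaccard concordance of topic-word bags). A synthetic-corpus generator
    with planted constant and seasonal topics supports recovery-based
    validation when the underlying clinical text cannot be shared.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    ggplot2,
    pheatmap,
    stats,
    utils,
    tools,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
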