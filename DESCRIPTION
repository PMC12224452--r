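Package: crossdecode
Title: Cross-Paradigm Searchlight Decoding of Semantic Composition in
    Source-Space MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Searchlight multivariate decoding of phrase versus single-noun
    source-space MEG epochs across a controlled two-word paradigm and a
    naturalistic listening paradigm.  Provides icosahedral source-space
    geometry with searchlight neighborhoods and spatiotemporal adjacency,
    a two-unit feed-forward classifier applied per searchlight and
    timepoint, group inference by threshold-free cluster enhancement
    (TFCE) with sign-flip max-statistic permutation, temporal
    generalization matrices with 2-D cluster-mass permutation tests,
    construction of seven word-level confound regressors (prosodic peaks,
    word rate, log frequency, surprisal, emotional valence and arousal)
    with mass-univariate residualization, classical-MDS neural state-space
    trajectories, embedding-side cross-context classification, and a
    seeded synthetic source-space data generator that emulates the
    statistical structure of the paradigm for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    nnet,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
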