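Package: megrsa
Title: Region-Based Decoding and Representational Similarity Analysis for
    Source-Space MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate pattern analysis for source-space
    MEG-like data confined to cortical atlas regions. Each region's vertex
    time courses are reduced to three spatial principal components,
    pseudo-trials are formed by averaging random draws of raw trials, and
    pairwise stimulus decoding with a regularized linear discriminant yields
    region-time accuracy maps. Empirical representational dissimilarity
    matrices built from the pairwise accuracies are compared against
    hypothesis-driven model RDMs by Spearman correlation with Fisher
    variance stabilization, followed by mass-univariate region-time t-maps
    with Benjamini-Hochberg false discovery rate control, onset extraction,
    bootstrap tests of decodability characteristics, a Bartlett
    dimensionality (MANOVA) test of model specificity, and a repetition
    analysis that projects regional activity onto classifier boundary
    weights and regresses segment amplitudes on presentation order. A
    synthetic-data generator with a ground-truth manifest emulates the
    study design (6 stimuli x 2 sections, 82 atlas regions) so every
    stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
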