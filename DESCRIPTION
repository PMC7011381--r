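Package: recoverymics
Title: Neutral and Deterministic Assembly in Recovering Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the balance of neutral (stochastic) and
    selective (deterministic) processes in the recovery of microbial
    communities after an environmental disturbance, built around a
    fish-microbiome cadmium-exposure study design. Fits the Sloan neutral
    community model by nonlinear least squares and classifies taxa against
    its 95% confidence band; computes generalized UniFrac phylogenetic
    beta diversity; runs PERMANOVA, MRPP and multivariate dispersion
    permutation tests with Benjamini-Hochberg control; builds Spearman
    sample-correlation networks with betweenness and eigenvector
    centrality; and includes a Hubbell-type neutral/selective community
    simulator that reproduces the study's factorial design with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
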