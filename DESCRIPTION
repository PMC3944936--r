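Package: psodt
Title: Gene Selection by Binary Particle Swarm Optimization with a C4.5
    Decision-Tree Fitness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for gene-expression classification.
    A binary particle swarm searches over gene subsets; each candidate subset
    is scored by the cross-validated accuracy of a C4.5 decision tree
    (gain-ratio threshold splits on continuous expression values) trained on
    the selected genes only. Includes a stratified k-fold evaluation harness
    with a nested (leakage-free) protocol, repeated-run summaries,
    gene-selection frequency analysis, a synthetic microarray generator with
    planted informative genes for validation, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
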