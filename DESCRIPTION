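Package: immunet
Title: Correlation Network Analysis of Immune Phenotype Panels
Version: 0.1.0
Authors@R:
    person("Dana", "Whitfield", email = "dana.whitfield@example.org",
           role = c("aut", "cre"))
Description: Builds thresholded Pearson correlation networks from
    subjects-by-immune-measures matrices, detects mesoscale communities with a
    degree-corrected stochastic block model combined with consensus
    clustering, and provides randomization tests for community composition
    (marked-node concentration, chain-like community topology, cross-network
    community overlap).  Includes a synthetic-data generator with planted
    block-correlation structure and realistic missingness, mean-imputation
    preprocessing, comparative PCA with automated outlier-measure removal,
    and an end-to-end, seed-reproducible pipeline with standard text-format
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
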