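Package: crosspath
Title: Weighted Pathway Crosstalk Analysis on Gene-Pathway-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores crosstalk between a fixed source pathway and candidate
    pathways on a bidirectional weighted network built from pathway gene
    sets, high-confidence protein-protein interactions, and transcriptomics
    derived edge weights. Gene weights are a logistic transform of
    differential-expression t-statistics; candidate pathways are screened by
    greedy enumeration of low-weight directed paths of three or more edges,
    scored as the sum of reciprocal path weights, and assessed by stratified
    permutation of pathway membership. Includes a companion hypergeometric
    overrepresentation analysis, disease-gene intersection and subnetwork
    extraction, and a synthetic-data generator with planted path structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
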