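Package: spokenet
Title: Clustering-Coefficient Scaling, Degree-Correlation Nulls, and
    Spoke-Like Modularity in Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to dissect why the per-degree clustering coefficient
    C(k) of many biological networks declines roughly as 1/k. Implements
    the deterministic hierarchical network model, configuration-model
    scale-free graphs with preferential-attachment super-hub injection,
    closed-form triangle-expectation theory, degree-preserving and
    joint-degree-preserving null models, a simulated-annealing null that
    matches a target triangle count under a fixed joint degree matrix,
    correlation profiles against randomized ensembles, super-hub
    detection, and construction of gene co-expression networks from
    expression matrices with missing values. Graphs are plain edge
    tibbles so every step composes with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
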