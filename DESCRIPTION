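Package: vaxscape
Title: Generative Landscape-Network Models of Vaccine-Hesitancy Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and estimators for studying how vaccine-hesitant
    communities come to cluster in space. Builds tunable Watts-Strogatz
    small-world landscapes of communities, generates hesitancy by social
    selection (attribute homophily annealed to a target Mahalanobis-based
    selection level) or social influence (bootstrap-percolation style
    diffusion under a neighbourhood tolerance), measures spatial clustering
    with a categorical assortativity coefficient on the spatial substrate,
    evaluates mitigation strategies (trait-and-conformity targeting, edge
    rerouting), and recovers the two process parameters from two-timepoint
    community data with bootstrap uncertainty.
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
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
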