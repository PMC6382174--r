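Package: phig
Title: Geometric Integrated Information and Minimum Information
    Bipartitions for Gaussian Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates geometric integrated information (Phi-G) for
    multivariate Gaussian time series from a lagged linear-regression model,
    and searches for the minimum information bipartition (MIB) either
    exhaustively or through a fast spectral-clustering candidate grid built
    from power-adjacency transforms of the correlation matrix. Includes
    generators for synthetic brain-like (Hebbian) connectomes, structurally
    cut networks and Watts-Strogatz graphs, simulators for coupled
    stochastic Rossler oscillators (with master-stability coupling bounds)
    and stable vector-autoregressive processes, structural graph metrics
    (global efficiency, Newman modularity, partition counting), and
    orchestration for the validation experiments relating network structure
    to information integration.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
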