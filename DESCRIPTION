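Package: swnet
Title: Statistical Small-World Tests for Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether ecological (trophic) networks display the
    small-world topology by comparing the empirical characteristic path
    length and clustering coefficient against 99 percent Monte-Carlo
    confidence intervals from matched Erdos-Renyi G(n,M) random graphs,
    alongside the Humphries-Gurney small-world-ness metric. Also fits six
    candidate degree-distribution models (Poisson, exponential, power law,
    truncated power law, lognormal, uniform) by maximum likelihood with
    AICc model selection, reads and writes food-web edge lists and
    adjacency matrices, and generates synthetic control networks
    (Watts-Strogatz, ring lattice, preferential attachment, uniform-degree
    configuration model).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
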