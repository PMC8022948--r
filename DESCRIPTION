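Package: neiqtl
Title: Interval Mapping of Neighbor Effects in Experimental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) mapping of neighbor effects, the
    dependence of an individual's phenotype on the genotypes of spatially
    proximate individuals. Implements hidden-Markov conditional genotype
    probabilities at markers and pseudomarkers for F2 intercross, backcross,
    and selfed recombinant inbred populations; conditional neighbor genotypic
    identity at a spatial scale; stepwise Haley-Knott genome scans for self
    and neighbor QTL effects with permutation thresholds and epistasis tests;
    and two-kernel variance-component models (AI-REML, binomial PQL) that
    partition phenotypic variance into polygenic self and neighbor effects
    and estimate the effective neighbor distance by the incremental-PVE
    (delta-PVE) criterion. Includes a simulation engine generating synthetic
    crosses, spatial maps, and neighbor-effect traits for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
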