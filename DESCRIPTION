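Package: oakdemog
Title: Multilocus Demographic Inference and Landscape Genetics for
    Temperate Oaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coalescent-based approximate Bayesian computation (ABC) over
    piecewise-exponential demographic scenarios, sequence diversity and
    neutrality statistics (haplotype diversity, nucleotide diversity,
    Watterson's theta, Tajima's D, the maximum-frequency-of-derived-mutations
    test, Hudson-Kaplan minimum recombination events), analysis of molecular
    variance (AMOVA) with permutation significance and pairwise F_ST,
    Mantel and partial Mantel isolation-by-distance/-ecology tests, and
    stepwise-AIC diversity-environment regressions.  Includes an HKY
    coalescent simulator and a synthetic-study generator emulating a
    21-population, three-locus phylogeographic sampling design, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    nnet,
    geosphere,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
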