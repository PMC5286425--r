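Package: isopop
Title: Genomic Isolation Profiling of Open and Isolated Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the genomic footprint of demographic isolation in
    diploid SNP panels. Detects runs of homozygosity with a sliding-window
    scanner and classifies their lengths by Gaussian-mixture modelling,
    computes identity-by-state sharing, identity-by-descent sharing (W_int),
    linkage-disequilibrium blocks, observed homozygosity and inter-locus
    dispersion per population, estimates contemporary effective population
    size from Burrows composite linkage disequilibrium with parametric
    confidence intervals, inverts the stationary inbreeding recursion
    dF = 1 - (1 - 1/2Ne)^t into time-since-isolation envelopes, and ranks
    populations by principal-component analysis of the intra-population
    measures together with distance-based multivariate structure analyses.
    Includes a forward-time founder-mosaic Wright-Fisher simulator that
    provides ground-truth identity-by-descent segments and closed-form
    expected inbreeding for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
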