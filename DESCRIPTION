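Package: hapscan
Title: Selection Scans, Haplotype Statistics and Introgression Tests for
    Phased Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic summaries (nucleotide diversity,
    weighted Weir-Cockerham FST, Tajima's D, linkage-disequilibrium decay),
    composite candidate-divergent-region outlier scans combining Z-transformed
    FST with log2 diversity ratios, EHH-family haplotype statistics (iHS, nSL,
    XP-EHH, XP-nSL) with frequency-bin standardization and window-proportion
    significance ranking, ABBA-BABA D statistics with block-jackknife standard
    errors, and a seeded forward Wright-Fisher simulator with recombination,
    split demography, introgression pulses and hard selective sweeps that
    emits phased VCFs together with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
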