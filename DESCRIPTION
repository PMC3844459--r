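Package: fampath
Title: Family-Based Pathway Association Testing with the Pedigree
    Disequilibrium Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway (gene-set) association analysis for family-based
    genome-wide association studies. Per-SNP pedigree disequilibrium test
    (PDT) statistics are computed from nuclear families with multiple
    siblings and possibly missing parents, reduced to per-gene scores, and
    tested for pathway enrichment with a weighted Kolmogorov-Smirnov-like
    running-sum statistic. Significance is assessed with a within-family
    sign-flip permutation null that preserves linkage disequilibrium by
    flipping one sign per family per chromosome, with permutation-based
    family-wise adjusted p-values and Benjamini-Hochberg false discovery
    rates. Includes readers for PLINK ped/map, gene location and GMT-style
    pathway files, and a synthetic generator of ascertained nuclear-family
    datasets under additive disease models for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
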