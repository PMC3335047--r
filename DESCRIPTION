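Package: rohscan
Title: Genome-Wide Homozygosity Association Scans for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control association mapping of runs of homozygosity (ROH).
    Estimates per-individual homozygote intensities in sliding SNP windows by
    tricube-weighted local linear smoothing, converts them to signed
    Kullback-Leibler deviations from the cohort median, and scans the genome
    with one-sided Wilcoxon rank-sum tests. Includes a synthetic case-control
    cohort simulator with an embedded disease-associated homozygous tract, a
    power-simulation study over effect size, tract length, heterozygous
    interference and window size, principal-component adjustment for
    population stratification, a run-length ROH caller with permutation
    association testing, and ROH-based disease-status prediction by
    discriminant analysis with cross-validation. Reads and writes PLINK text
    pedigree files, genotype TSV and BED regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
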