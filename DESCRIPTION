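Package: rohdice
Title: Enumeration of Runs-of-Homozygosity Diplotype Clusters with the
    Positional Burrows-Wheeler Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds clusters of runs-of-homozygosity (ROH) diplotypes in
    diploid biallelic genotype panels: sets of at least W individuals that
    share an identical homozygous diplotype over at least L consecutive
    variant sites.  Genotypes are compressed to a pseudo-haplotype panel,
    matching blocks are enumerated with a positional Burrows-Wheeler
    transform (PBWT) scan under either a width-maximal or a length-maximal
    objective, and clusters are post-processed with a per-member
    heterozygosity filter and consensus-based merging.  Also provides a
    coalescent-simulation evaluation harness with identity-by-descent
    ground truth, planted-cluster fixtures, detection accuracy and power
    metrics, and cluster-level association and linkage statistics
    (chi-squared tests, D and D-prime, hotspot/coldspot scans, and a
    phenotype-simulation power comparison against single-SNP association
    models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
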