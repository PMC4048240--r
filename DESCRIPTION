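Package: fsmapr
Title: High-Density Genetic Linkage Maps for Outbred Full-Sib Families
Version: 0.1.0
Authors@R:
    person("fsmapr", "developers", email = "fsmapr@example.org", role = c("aut", "cre"))
Description: Construction of high-density genetic linkage maps from
    error-prone, high-missingness genotype data of a single outbred
    full-sib (CP) family.  Implements single-linkage grouping on a
    chi-square derived independence LOD, two-point recombination and
    linkage-phase inference by anchoring, marker ordering by spatial
    sampling plus simulated annealing on the sum of adjacent
    recombination fractions, blocked Gibbs multipoint estimation of
    interval recombination fractions, and iterative singleton-based
    genotyping-error correction and missing imputation with a k-nearest
    neighbour vote.  A full-sib family simulator with known truth
    (marker placement, interference-free meioses, error/missing
    injection, depth-dependent miscalls) supports benchmarking, and
    evaluation utilities report singleton rates, order correlations,
    map lengths, heat-map and haplotype-map exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
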