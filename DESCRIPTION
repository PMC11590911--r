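Package: lddecay
Title: Linkage Disequilibrium Decay Analysis for Dense SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterising linkage disequilibrium (LD)
    decay in diploid SNP genotype panels. Reads PLINK text PED/MAP files,
    applies the standard locus-level quality-control cascade (autosome
    restriction, Hardy-Weinberg exact test, call rate, minor allele
    frequency), estimates two-locus haplotype frequencies from unphased
    genotypes by expectation-maximisation, and computes D, D-prime, r-squared
    and the finite-sample corrected r-squared for all syntenic marker pairs.
    Pairwise estimates are aggregated into distance-class, point-distance,
    per-chromosome and adjacent-marker decay summaries, per-population minor
    allele frequency spectra, cross-population monomorphic-marker overlap,
    and a Cohen-kappa style genotype concordance quality score for duplicate
    or called-versus-true sample pairs. A synthetic-panel generator with a
    latent autoregressive Gaussian copula and a two-locus Wright-Fisher
    simulator provide fully reproducible inputs for validation against
    population-genetic theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
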