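Package: oakphylo
Title: Phylogeography Toolkit for Andean Oak Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for microsatellite phylogeography of
    Quercus humboldtii and similar montane trees: genotype-table I/O and
    haplotype extraction, per-population diversity statistics (h, v,
    rarefied richness, heterozygosities), marker quality control (HWE and
    linkage permutation tests, EM null-allele estimation, Weir-Cockerham
    FST with ENA correction), hierarchical AMOVA under infinite-allele and
    stepwise mutation models, NST/GST and RST allele-size permutation
    tests, minimum spanning haplotype networks, geographically regularized
    ancestry estimation with cross-validated choice of K, approximate
    Bayesian computation over three single-population demographic
    scenarios with a built-in stepwise-mutation coalescent simulator, and
    graph-based landscape connectivity (equivalent connectivity area) on
    habitat-suitability rasters.  A synthetic-data module generates
    genotypes, coordinates and rasters with known truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
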