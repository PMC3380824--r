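Package: introgrescan
Title: Multilocus Tests of Adaptive Introgression from Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises adaptive introgression between
    hybridising species from per-locus phased haplotype alignments. Implements
    the shared-polymorphism linkage disequilibrium test of gene flow
    (x = Dss - Dsx) with coalescent-simulation null distributions, one-factor
    analysis of molecular variance (AMOVA) with permutation significance,
    neighbour-joining genealogies with bootstrap support, fixed-topology
    GTR+I+Gamma likelihood evaluation with the Shimodaira-Hasegawa topology
    test, and a two-population isolation-with-migration coalescent simulator
    with infinite-sites mutation that generates phenotype-structured
    multi-locus study datasets. A configuration-driven pipeline reproduces the
    standard analysis tables end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
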