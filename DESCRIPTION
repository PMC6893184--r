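Package: recsel
Title: Recurrent Selection Simulations under Engineered Recombination
    Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulation of biparental
    plant breeding programs under normal and experimentally increased
    meiotic recombination. Chromosomes carry continuous founder-origin
    mosaics in genetic (cM) space; crossovers are drawn from the Haldane
    (Poisson) model or a stationary gamma-renewal model with interference.
    Recombination landscapes are represented as monotone Marey maps
    (physical Mb to genetic cM) and can be modified multiplicatively
    (shape-preserving, 'HyperRec'-like) or additively (pericentromere
    warming, allotriploid-'boosted'-like). Traits are additive with
    gamma-distributed QTL amplitudes sampled at gene positions, with
    optional coupling or repulsion of founder linkage phase. Selection
    schemes include recurrent selection on heterozygous populations and a
    doubled-haploid scheme, under phenotypic or RR-BLUP genomic selection
    with configurable recalibration, and replicated experiments report
    genetic gain, genetic variance and gain ratios with confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
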