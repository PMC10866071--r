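Package: hatchscan
Title: Selection-Signature Scans for Multi-Generation Hatchery Breeding Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide diversity and differentiation estimators and a
    windowed theta-pi-ratio by Fst selection-signature scan for laboratory
    breeding experiments on bivalves and other high-fecundity aquaculture
    species. Implements per-locus and sliding-window nucleotide diversity,
    Tajima's D, Weir-Cockerham Fst, inbreeding coefficients, genomic
    relationship matrices, PCA, identity-by-state neighbor-joining trees,
    and linkage-disequilibrium decay; classifies windows under positive or
    negative selection by joint empirical quantiles of the log2 diversity
    ratio and Fst with permutation significance; maps candidate regions to
    genes and compares relative expression between generations. Ships a
    forward-time diploid Wright-Fisher breeding simulator with separate
    sexes, recombination, reproductive skew, and viability selection that
    emits genotype matrices with known truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
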