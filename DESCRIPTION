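Package: genonet
Title: Genotype Networks of Phased Haplotypes for Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds genotype networks from phased single-nucleotide variant
    haplotypes: distinct haplotype strings are nodes and edges join strings at
    Hamming distance one. Computes per-window network statistics (number of
    vertices, average path length, number of components, average degree) in a
    sliding-window genome scan, with minor-allele-frequency filters, functional
    annotation classes, BED exclusion masks, genetic-map covariables, and
    browser-track output. Includes a forward-in-time Wright-Fisher simulator of
    multi-population phased haplotype samples with an optional selective sweep,
    plus the statistical analyses used to study the method: subsampling curves,
    property correlations, annotation-class analysis of covariance, and
    neutral-versus-sweep scenario comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
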