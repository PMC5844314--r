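Package: sweepscan
Title: Selective-Sweep Scanning and Population-Genomic Analysis of
    Resequencing Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream population-genomic analysis of multi-sample variant
    calls: SNP filtering and functional annotation against gene models,
    windowed nucleotide diversity (theta-pi) and Hudson FST with joint
    top-quantile selective-sweep calling, p-distance neighbor-joining
    phylogeny with site-resampling bootstrap, principal component analysis
    with allele-frequency scaling, linkage-disequilibrium decay curves from
    unphased genotypes, and binomial over-representation tests with
    Benjamini-Hochberg correction.  A Balding-Nichols genotype simulator
    with planted sweeps, distance-decaying linkage and transition-biased
    mutation supplies ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
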