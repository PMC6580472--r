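Package: germchrome
Title: Germline Nuclear Chromatin and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream genomic analyses for comparing chromatin and
    nuclear transcriptomes between isolated germ nuclei (IGN) and somatic
    tissue (SOM) in C. elegans: rule-based assignment of histone
    modification ChIP peaks (H3K27ac, H3K4me3) to representative target
    genes, metagene signal profiling around TSSs and across scaled gene
    bodies, chromosome-wise peak distribution statistics, hypergeometric
    gene-category enrichment, nuclear-retention expression ratios,
    intron-read statistics with TP10M normalization, and modification
    status by expression cross-tabulation. Includes a seeded synthetic
    data generator that emulates the statistical structure of two-tissue
    nuclear ChIP-seq/RNA-seq studies so the whole pipeline runs without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
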