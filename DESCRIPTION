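Package: invex
Title: Inversion-Karyotype Analysis of Testis and Liver Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for bulk RNA-seq studies of chromosomal
    inversion karyotypes (AA, AB, BB) across testis development and in liver.
    Provides histology-based developmental staging via a maturation index,
    karyotype-contrast differential expression with TMM normalization,
    mean-variance precision weights and empirical-Bayes moderated t-statistics
    under a global multiple-testing rule, sliding-window genomic enrichment of
    differentially expressed genes, chromosome-Z bias tests, inversion-haplotype
    allele-specific expression from VCF allelic depths, heterokaryotype
    dominance-pattern classification, genotype polarization with
    fixed-difference block segmentation for breakpoint delineation, and a
    synthetic-data generator that plants all effects with a machine-readable
    truth record.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
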