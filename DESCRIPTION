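Package: apaqtl
Title: Mapping Genetic Determinants of Alternative Polyadenylation from
    RNA-Seq and Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the relative expression of alternative 3' UTR
    isoforms generated by tandem alternative polyadenylation (the m/M
    value, a length-normalised short/long isoform ratio computed from
    reads over PRE and POST segments of the terminal exon), maps cis
    genetic variants associated with that ratio (apaQTLs) with a
    permutation-calibrated linear model and Benjamini-Hochberg
    correction, and interprets significant variants through LD-aware
    logistic enrichment analyses (chromatin states, gene regions,
    cis-regulatory domains, GWAS traits) and allele-aware calls of
    polyadenylation-signal, microRNA-seed and RNA-binding-protein motif
    alteration. Includes a seeded synthetic-data generator emulating the
    statistical structure of a population RNA-seq + whole-genome
    sequencing study, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    yaml
Config/testthat/edition: 3
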