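Package: morna
Title: Quantification of MicroRNA-Offset RNAs and Seed-Window Target Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microRNA-offset RNAs (moRs) and mature miRs from
    aligned small-RNA sequencing reads using strand-aware coordinate windows
    derived from miRBase annotations, with even allotment of reads among
    nearby pri-miR loci and reads-per-million-region-reads (RPMR)
    normalization. Enumerates candidate 7-nt seed windows of a small RNA,
    scans 3'UTR sequences for seed matches, cross-tabulates predicted targets
    against microarray differential-expression classes with an exact binomial
    enrichment test, and models bulged sponge binding sites for small-RNA
    loss-of-function constructs. Includes seeded synthetic-data generators
    (annotations, aligned reads, UTR sets, differential-expression tables)
    with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
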