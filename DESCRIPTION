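Package: andromics
Title: Transcriptome and Small RNA Analysis of Microspore Embryogenesis Induction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis pipeline for staged bulk RNA-seq and small-RNA
    sequencing experiments on stress-induced microspore embryogenesis
    (androgenesis). Implements zero-preserving quantile normalization scaled to
    reads per million quantile-normalized reads (rpmqn), restructuring of de
    novo assembled contigs into transcript units via best cDNA hits, per-stage
    expressed-set calling with three-set Venn partitioning, a
    filter-cascade differential expression caller (minimum expression,
    fold change, replicate coefficient of variation, Student's t-test with
    Benjamini-Hochberg FDR control), k-means clustering of z-normalized stage
    profiles under centered-correlation dissimilarity, bootstrap gene ontology
    term enrichment, and small-RNA read collapsing, length profiling, exact
    mature-miRNA matching and target expression anticorrelation filtering.
    Includes a fully seeded synthetic-data generator with ground-truth labels
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
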