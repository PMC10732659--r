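Package: rrhp
Title: Reduced-Representation 5-Hydroxymethylcytosine Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of reduced-representation 5-hydroxymethylcytosine
    profiling (RRHP) data, in which sequencing tags anchored at CCGG
    (MspI) sites measure 5hmC abundance. Extracts CCGG-anchored tag
    observations from aligned reads, builds site-by-sample count
    matrices, applies a two-stage low-signal filter, and tests for
    differential hydroxymethylation with a log2-CPM transform carrying
    observation-level precision weights, weighted least-squares group
    models, empirical-Bayes variance moderation and Benjamini-Hochberg
    false discovery control. Also provides genomic feature annotation
    with nearest-TSS assignment, gene-set over-representation, allelic
    and haplotype association tests for full-sib designs, conserved
    window detection with IUPAC motif scanning, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    methods,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
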