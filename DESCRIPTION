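Package: scdeplete
Title: Design and In Silico Simulation of CRISPR-Based Depletion for
    Single-Cell RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing CRISPR sgRNA panels that remove abundant,
    uninformative molecules (ribosomal RNA, mitochondrial and ribosomal
    protein genes, non-variable housekeeping genes, and intergenic hotspot
    intervals) from droplet single-cell RNA-seq libraries, and for
    simulating the depletion in silico at both read and UMI-count level.
    Includes guide enumeration against NGG PAM sites with composition and
    mismatch-based off-target filtering, panel curation from count
    matrices and read coverage, count-level depletion with multinomial
    re-allocation proportional to relative abundance, library
    recomposition metrics (read buckets, top-N UMI fractions, per-cell
    complexity, Marchenko-Pastur signal components), panel applicability
    scoring (tau tissue specificity, preranked enrichment, marker
    overlap), pseudobulk off-target QC, and a synthetic-fixture generator
    so the whole pipeline runs on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
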