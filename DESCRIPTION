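Package: subdom
Title: Subgenome Dominance Analysis for Allopolyploid Multi-Omic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing subgenome dominance in allopolyploid
    genomes from annotation- and summary-level omics data. Implements
    homoeolog pairing by collinear anchor chaining, sliding-window
    fractionation profiles, TPM-based expressed-gene filtering, a
    negative-binomial Wald test for homoeolog expression bias and
    differential expression, transposable-element load and methylation
    metaprofiles, accessible-chromatin-region (ATAC) positional and
    conservation classification with progenitor ancestry attribution,
    and windowed MeRIP (m6A) IP-versus-input peak calling with
    condition comparison and expression integration. A seeded
    synthetic allotetraploid data generator with truth tables makes
    every stage testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
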