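Package: mtaltorf
Title: Discovery of Alternative Open Reading Frames in Circular
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enumerates open reading frames in all six frames of a circular
    genome under configurable genetic codes, including the vertebrate
    mitochondrial code with AGA/AGG read as arginine, classifies them
    against reference annotations (sense frameshift, antisense, rRNA- or
    tRNA-resident, intergenic), computes peptide molecular masses, performs
    in-silico tryptic digestion to build mass-spectrometry query lists, and
    shades ortholog conservation from progressive global alignments. A
    seeded simulator plants reference genes and alternative ORFs into
    synthetic circular genomes with a machine-readable truth table, so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
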