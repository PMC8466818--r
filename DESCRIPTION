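Package: cansynth
Title: Classification, In-Silico Genotyping and Expression Analysis of
    Cannabinoid Synthase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating near-identical paralogs of the
    cannabinoid synthase gene family (THCAS, CBDAS, CBCAS) in Cannabis
    sativa. Classifies coding sequences by clade-diagnostic SNPs, annotates
    nucleotide and amino-acid substitutions against reference sequences,
    predicts multiplex PCR products and interprets B-locus chemotype
    markers, validates primer specificity in silico, builds neighbor-joining
    trees with bootstrap support, and quantifies transcript levels from
    RT-qPCR plates via the standard-curve method with reference-gene
    stability ranking and geometric-mean normalization. A synthetic-data
    module generates gene-family panels and qPCR plates with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
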