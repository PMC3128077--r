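Package: iiascout
Title: Discovery of Small Unannotated Subunit IIa Genes in B-Family
    Heme-Copper Oxidase Operons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect small unannotated open reading frames
    (micro-ORFs) directly upstream of cytochrome c oxidase subunit II
    genes, the genomic location of the single-helix subunit IIa of
    B-family (ba3-type) heme-copper oxidases. Provides windowed
    Kyte-Doolittle hydropathy prediction of transmembrane segments,
    detection of single-nucleotide indels that disrupt reading frames
    (frameshift correction), a conserved-motif scanner and pairwise
    global alignment summaries for candidate validation, intact-protein
    MALDI mass assignment with charge-carrier, adduct and neutral-loss
    hypotheses at ppm tolerance, in-silico tryptic digestion with
    peptide-mass-fingerprint coverage, theoretical b/y fragment-ion
    series with y-ion ladder sequence readout, a cross-genome survey
    report, and a seeded synthetic-data generator (operon genomes and
    mass spectra with truth files) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
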