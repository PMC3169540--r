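Package: nidoscan
Title: Nidovirus Genome Annotation, TRS Discovery, Frameshift Signal
    Scanning and Genome-Size Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative-genomic characterization of
    nidovirus-like positive-strand RNA virus genomes: open reading frame
    and untranslated-region annotation with protein-level feature reports,
    discovery of candidate transcription-regulating sequences (TRS) by
    constrained maximal exact repeat detection and near-perfect
    leader/body pairing, localization of -1 programmed ribosomal
    frameshift signals (slippery heptamer scanning plus stem-loop
    detection by base-pair maximization), subgenomic mRNA size
    prediction, and a product-of-binomials threshold test linking a
    binary lineage trait (such as exoribonuclease presence) to genome
    size. A synthetic genome generator with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
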