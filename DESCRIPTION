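Package: presenteR
Title: Design and Deconvolution of Pooled MHC-I Minigene Immunogenicity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled drop-out screens of MHC class I ligand
    immunogenicity built on self-barcoding minigenes. Designs wild-type and
    single-residue-mutant 8-mer peptide libraries from a proteome under a
    predicted-affinity filter, encodes each peptide as a minigene oligo (ER
    signal sequence + epitope) whose coding sequence doubles as its own
    sequencing barcode, deconvolutes amplicon reads into per-minigene counts
    and relative abundances, compares pretumor and tumor samples with
    pseudocounted log2 fold changes and a LOESS trend, and analyses two-color
    subclone mixture experiments with a one-sample t-test on log10 fold
    changes to estimate the clonal fraction below which immune depletion is
    not detected. A synthetic-data generator (proteomes, multinomial
    injection/growth/sequencing bottlenecks with clonal-fraction-gated
    depletion, two-color mixtures, error-bearing amplicon reads) makes the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
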