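Package: mipannot
Title: Annotation and Functional Prediction for Plant Aquaporin (MIP) Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for annotating plant major intrinsic protein (MIP,
    aquaporin) gene families from protein sequences and gene models.
    Classifies proteins into the PIP, TIP, NIP, SIP and XIP subfamilies with a
    transparent residue-rule cascade, extracts diagnostic residues (dual NPA
    motifs, the aromatic/arginine selectivity filter, Froger's positions and
    specificity-determining positions) by global alignment to a reference
    template, predicts transported substrates by rule matching with
    novel-variant flagging, summarises gene exon-intron architecture and
    protein physicochemical properties, and computes RPKM-based tissue
    expression summaries. Ships table fixtures for the castor bean aquaporin
    family and a synthetic-data generator with known ground truth so that
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    jsonlite
Config/testthat/edition: 3
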