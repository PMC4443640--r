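Package: splfam
Title: Mining, Classification and Expression Analysis of SBP-Domain (SPL) Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for characterizing the SQUAMOSA PROMOTER
    BINDING PROTEIN-LIKE (SPL) transcription-factor family in a plant genome:
    profile-based mining of SBP-domain proteins from a FASTA/GFF3 annotation,
    scanning spliced transcripts for miR156 binding sites under a positional
    mismatch rule, locating sites in the 5'UTR/CDS/3'UTR, three-way subgroup
    classification, antisense-overlap detection and ortholog evidence scoring,
    neighbor-joining phylogeny of SBP domains from corrected protein distances,
    and the expression arithmetic used in fruit-load studies (FPKM, TMM
    normalization factors, qPCR relative expression, one-way ANOVA with
    Tukey-Kramer letter displays). A seeded synthetic-data generator emits
    genomes, annotations, count matrices and Ct tables with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
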