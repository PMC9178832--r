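Package: ervscape
Title: Discovery, Annotation and Molecular-Clock Dating of Endogenous
    Retrovirus Loci
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes an endogenous retrovirus (ERV) group in a genome
    assembly the way genome-wide HERV surveys do: seed-and-extend homology
    search against a region-annotated proviral reference (LTR5-gag-pro-pol-
    env-LTR3), classification of hits into proviruses and solo LTRs,
    per-region structural integrity and indel annotation, LTR-LTR and
    region-versus-consensus molecular-clock integration dating,
    chromosomal-distribution tests, genomic-context classification,
    GREAT-style basal-plus-extension regulatory-domain gene association with
    hypergeometric over-representation analysis, position-weight-matrix
    scanning at a relative profile score threshold, and primer-binding-site
    extraction and tRNA typing.  Includes a seeded synthetic-genome
    generator that plants proviruses and solo LTRs with known age, deletions
    and genomic context, and packaged transcriptions of a published HML-9
    locus catalog for replaying its summary statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
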