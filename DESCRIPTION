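Package: uorfconnect
Title: Conservation Scoring, Splice-Junction Grafting and Structure Triage of
    Upstream Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether upstream open reading frames (uORFs)
    annotated on protein-coding transcripts are better explained as novel
    first coding exons of the downstream gene. Implements an additive 0-7
    cross-genome conservation rubric reconciling genomic and transcriptomic
    sequence matches with a protein-level fallback, construction of
    "uORF-connected transcripts" by splicing a donor inside the uORF to an
    acceptor in the downstream coding sequence (from read-coverage-backed
    junction evidence or scored candidate junctions), three ORF-validity
    filters, and average-pLDDT structure gating of the resulting novel
    proteins. Ships a seeded synthetic-fixture generator emulating multi-locus
    genomes with controlled conservation, splicing and structure outcomes so
    the full pipeline runs and is tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
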