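Package: artrkit
Title: Analysis of Antibody-Guided In Situ Reverse-Transcription RBP
    Binding-Site Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested toolkit for profiling RNA-binding-protein (RBP)
    binding sites from antibody-guided in situ reverse-transcription
    sequencing libraries. Covers the full computational path from raw
    barcoded, UMI-tagged paired reads to binding sites and binding
    dynamics: demultiplexing, adapter/quality trimming, UMI-exact
    deduplication, strand-separated Poisson peak calling against input
    controls with Benjamini-Hochberg correction, feature annotation and
    motif-distance statistics, gene-level enrichment by the
    Mantel-Haenszel common odds ratio with the Cochran-Mantel-Haenszel
    test, and fuzzy c-means clustering of binding time courses. A
    synthetic-data generator emulates the assay (planted motif-anchored
    sites, expression-proportional background, PCR duplicates, UMIs,
    sample barcodes, adapter read-through) so that every stage can be
    verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
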