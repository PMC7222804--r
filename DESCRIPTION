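Package: mitocpg
Title: CpG Islands and CpG-Rich Regions in Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strand-aware detection and annotation of CpG islands and CpG-rich
    regions in animal mitochondrial genomes. Implements a sliding-window island
    caller based on the observed/expected CpG ratio and percent C+G criteria, a
    running-sum maximal-scoring-segment detector of CpG-rich regions, attribution
    of detections to annotated mtDNA features (protein genes, tRNAs, rRNAs,
    D-loop, replication origin), per-species and cross-species comparative
    summary tables, and a seeded generator of mitochondria-like synthetic
    genomes with planted CpG islands for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
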