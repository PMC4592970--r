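Package: sonic4C
Title: Sonication-Based 4C-seq Interaction Mapping and Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sonication-based circularized chromosome
    conformation capture sequencing (4C-seq). Turns paired-end reads or
    pre-aligned end-tag pairs into bait-interacting distal sites (20-bp tag
    extraction, MAPQ filtering, bait-junction classification, 100-bp merging,
    singleton removal), calls significantly enriched interacting domains with
    a windowed z-score and a permutation-based false discovery rate, measures
    replicate concordance (binned-count Pearson correlation and the relative
    distance statistic), and runs anchor-centric integrative analyses against
    epigenomic feature tracks (peak and ChIP tag enrichment, replication
    timing, distance-to-TSS densities, gene expression). Includes a fully
    deterministic synthetic-data generator with a ground-truth table so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
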