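Package: splicescape
Title: Splice-Junction Catalogs and Alternative-Splicing Classification for
    Compact Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for discovering and classifying alternative
    splicing from spliced paired-end RNA-seq alignments against
    intron-dense fungal genomes. Filters alignment pairs, extracts and
    corrects a splice-junction catalog (hierarchical branch-point motif
    search, polypyrimidine-tract detection, position-weight-matrix
    splice-site scoring, same-length overlap correction), clusters
    junctions and classifies every cluster into an event taxonomy
    (intron retention with retention ratios, alternative 5'/3' splice
    sites and their multi-site and complex generalisations), assembles
    coverage-based transcript models with ORF calls, and computes
    feature statistics and isoform-usage regressions. A seeded synthetic
    genome and read simulator with a planted truth set makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomeInfoDb,
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
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
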