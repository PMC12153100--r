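Package: devhet
Title: Comparative Heterochrony Analysis of Developmental Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting heterochronic shifts in gene expression
    between species from bulk developmental RNA-seq time courses. Expression
    profiles are standardized and soft-clustered with fuzzy c-means, the
    number of clusters is selected with the Calinski-Harabasz index, clusters
    are classified into developmental phases (early/cleavage vs
    late/post-cleavage, with pre-/post-larval sub-phases) from their
    expression maxima, and single-copy orthologs are cross-tabulated between
    species into quadrant tables and heterochronic gene sets. Also includes
    marker-pair ("cyclone"-style) cell-cycle phase scoring adapted to bulk
    samples, a census of histone H2A.X C-terminal SQ[DE][FY] motif variants
    across proteomes with per-phylum and lifestyle aggregation, sequence-logo
    information content, and a synthetic-data generator with planted cluster
    structure, heterochronic shifts, phase-dependent markers and C-terminal
    motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
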