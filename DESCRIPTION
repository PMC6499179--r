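Package: wgdetect
Title: Multi-Evidence Inference of Whole-Genome Duplication Status and Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers whole-genome-duplication (WGD) status and timing across
    related species from several independent lines of evidence: modal peaks in
    synonymous-substitution (Ks) distributions estimated with the
    Nei-Gojobori (1986) counting method, Ks-filtered Markov clustering of
    homology graphs into gene families, duplication/speciation labeling of
    gene trees by the species-overlap rule, gene-family copy-number ratio
    statistics, algebraic solving of consensus branch lengths from modal Ks
    values, quota-based synteny depth screening, and modal chromosome-count
    analysis. A synthetic genome-evolution generator (including an
    allopolyploidy model with lineage-specific rate multipliers, post-WGD
    fractionation, and tandem duplication) exercises every stage against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    methods,
    phangorn,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
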