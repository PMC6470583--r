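Package: dupliTE
Title: Transposable-Element Neighborhoods and Epigenetic Divergence of
    Duplicated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the transposable-element (TE) neighborhood of
    protein-coding genes (insertion density and nucleotide coverage in the
    gene body plus 2 kb flanks), classifies genes into five TE-neighborhood
    categories (a TE-free rule plus k-medoids clustering of the remaining
    genes), summarizes per-gene epigenetic state (mean histone fold
    enrichment for six marks, gene-level methylation status from
    hypo/hyper-methylated regions) and expression divergence between
    duplicated gene pairs (FPKM to TPM conversion and the Manhattan
    expression-divergence statistic), and tests whether duplicated genes
    share TE neighborhoods more often than expected using a 15-cell
    unordered pair-context table with a Monte-Carlo chi-squared
    goodness-of-fit test. Includes a seeded synthetic-data generator that
    emulates the full input bundle (genes, TE insertions, families with
    dS/dN, methylation regions, histone enrichment tracks, FPKM tables) so
    the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
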