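Package: g4tools
Title: Genome-Wide G-Quadruplex Motif Discovery and Distribution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative G-quadruplex (G4) motifs in genome sequences
    using the quadparser-style perfect pattern (G3+L1-7)3+G3+, multimeric
    (>= 8 G-stem) variants, and bulged imperfect motifs, on both strands.
    Assigns motifs to gene structural elements read from GFF3 annotation,
    computes per-feature densities, metagene positional profiles around the
    start codon and first intron with moving-average smoothing, shuffle-based
    genic enrichment, GO term association and enrichment statistics, and SNP
    disruption classification. Includes a seeded synthetic genome generator
    with planted motifs, genes, transposable elements and SNPs plus a truth
    ledger, so the whole pipeline can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
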