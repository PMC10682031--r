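Package: diffAS
Title: Differential Alternative Splicing from Junction Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies alternative-splicing events (cassette,
    multi-cassette, alternative donor/acceptor sites, alternative first/last
    exons, mutually exclusive exons, intron retention) from a transcript
    annotation, quantifies per-event inclusion levels (PSI) from splice-junction
    read counts in a two-condition design, scores differential splicing by
    combining a junction-count Fisher exact test with an exon/gene coverage
    Fisher exact test (Fisher's method, Benjamini-Hochberg adjustment, a
    fold-change rule with a condition-exclusivity clause), and performs
    hypergeometric over-representation analysis on the differentially spliced
    genes. A seeded synthetic-data generator emulates the two-condition
    junction-read design with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
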