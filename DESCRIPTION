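Package: ripstab
Title: Degenerate Motif Enrichment in RIP-Seq Peaks and mRNA Stability
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how an RNA-binding protein stabilises its
    target mRNAs. Scans RIP-seq peak sequences for degenerate (IUPAC) G-rich
    motifs and tests their enrichment against a randomisation null of
    resampled sequence sets matched in number and length distribution, with
    empirical and rank-based p-values. Estimates mRNA half-lives from
    actinomycin-D chase qPCR time courses by log-linear regression, performs
    relative (delta-delta-Ct) and absolute (standard-curve) qPCR
    quantification, and nominates candidate target transcripts by
    intersecting knockdown-downregulated genes with RIP-enriched genes under
    explicit thresholds. A seeded synthetic-data generator produces peak
    sequence sets with planted motifs, exponential decay courses with
    multiplicative noise, and paired gene tables with known true targets,
    so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
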