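Package: uprshift
Title: Promoter Motif Scanning and Expression-Shift Analysis for ER-Stress Regulons
Version: 0.1.0
Authors@R: person("UPRshift", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to analyse the transcriptional side of the endoplasmic-reticulum
    stress response: classify genes as up-, down- or unchanged from
    control-versus-stress expression ratios, scan strand-aware promoter windows
    around annotated transcription start sites for degenerate-consensus bZIP/Atf4
    binding motifs (the CRE core TGACGT and the TT(G/T)CATCA(G/T) element),
    quantify motif-regulation concordance with an enumeration-based two-sided
    Fisher exact test, perform in-silico reporter-style promoter mutagenesis,
    and compute reference-gene-normalised qPCR relative expression with paired
    t-tests. A seeded synthetic-data generator (motif-free backgrounds with
    planted sites, expression tables with planted fold changes, Ct tables) lets
    every stage be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
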