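Package: pigmentExpr
Title: Expression Quantification and Enrichment Classification for
    Zebrafish Pigment Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse bulk mRNA-seq tag counts from purified
    zebrafish pigment cells (melanocytes, iridophores, retinal pigmented
    epithelium) against whole-embryo baselines. Builds non-redundant
    transcript databases by identity/coverage collapse, converts tag
    counts to RPKM, computes detection and sequencing-depth saturation
    curves, windowed Pearson correlations of expression profiles,
    per-gene Student's t statistics and fold changes with explicit zero
    semantics, and a declarative multi-criteria enrichment classifier
    (shared, pairwise-shared, cell-type specific, and high-stringency
    filters). Includes a negative-binomial count simulator with planted
    enrichment classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
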