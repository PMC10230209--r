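Package: uidlink
Title: Hash-Based Anonymous Identifiers for Roster Deduplication and Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates anonymous unique identifiers for health and welfare
    service rosters by hashing a small set of personal key fields (gender and
    military service number) with SHA-256, and validates the identifier against
    the single-field gold standard. Provides the full validation procedure:
    primary/duplicate case flagging, 2x2 cross-tabulation, sensitivity and
    specificity with exact Clopper-Pearson confidence intervals, Pearson
    chi-square, and a single-threshold ROC/AUC; one-to-one linkage of
    deduplicated rosters across datasets; and a synthetic roster generator
    with latent ground truth for end-to-end validation of every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
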