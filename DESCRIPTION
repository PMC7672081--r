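Package: scscreen
Title: Synergistic Chemo-Sensitivity Screening of Gene Pairs Against Drug
    Response Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for synergistic chemo-sensitivity (SCS)
    interactions: gene pairs whose joint damaging mutation sensitises cancer
    cell lines to a drug. Builds binary damaging-mutation matrices from
    annotated coding variants (loss-of-function, SIFT/PolyPhen-filtered
    missense) and homozygous copy-number deletions, screens every gene pair
    against per-drug log-IC50 profiles with pooled t tests and drug-wise
    Benjamini-Hochberg correction, combines recurrent partner genes of an
    anchor gene for burden analyses, clusters drug/gene and drug/tissue
    matrices, and validates candidate pairs in patient cohorts with
    Kaplan-Meier, log-rank and Cox proportional-hazards survival models.
    Includes a synthetic-data generator that plants known effects so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
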