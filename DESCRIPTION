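Package: agesig
Title: Cross-Species Conserved Aging Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying conserved transcriptomic
    signatures of aging across species and tissues from bulk RNA-seq read
    counts. Provides TPM normalization, a simplified negative-binomial Wald
    test for differential expression with Benjamini-Hochberg adjustment,
    ortholog-anchored gene preselection, filters for conserved and
    tissue-exclusive age-regulated signatures, coefficient-of-variation
    analysis of expression variability across age groups, majority-vote
    functional profiling of differentially expressed genes, and
    silhouette-based cluster-separation scores. Includes a negative-binomial
    study simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
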