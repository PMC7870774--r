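Package: txsim
Title: Transcriptome Similarity of Cell Models via Non-DEGs and Differential Transcript Usage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for scoring how closely in vitro cell model
    transcriptomes resemble a reference tissue. Given gene- and isoform-level
    RNA-seq quantification for a large reference group and one or more small
    test groups, the package normalizes counts (median-of-ratios), runs a
    per-gene negative-binomial Wald test, derives non-differentially-expressed
    genes (non-DEGs) as a similarity metric, bootstrap-selects the most
    reference-like replicates, applies a differential-transcript-usage (DTU)
    filter cascade with one-way ANOVA on isoform usage percentages to refine
    the non-DEG set, and scores pathway gene-set coverage. A truth-labelled
    negative-binomial/multinomial simulator generates gene and isoform counts
    with the study design's structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
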