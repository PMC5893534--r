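Package: pathfabric
Title: Pathway-Level Regulation and Recovery Scoring for Treatment
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies pathway-level transcriptome alteration and
    treatment recovery from replicated expression cohorts. Implements
    per-gene adaptive regulation calls (signed fold-change against a
    variability-derived cut-off combined with a heteroscedastic t-test),
    the Weighted Pathway Regulation (WPR) alteration score, the Gene
    Expression Recovery (GER) and Pathway Restoration Efficiency (PRE)
    treatment-recovery scores, replica-wise gene coordination networks,
    a noncentral-F ANOVA sample-size calculator, and a synthetic
    microarray-cohort generator with a planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
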