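Package: palrank
Title: Pathway Activation Scoring and Expression-Based Ranking of Targeted
    Cancer Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores tumor RNA-seq profiles against a normal-tissue reference
    using pathway activation levels (PAL): signed, activator/repressor-weighted
    means of log10 case-to-normal expression ratios over pathway member genes.
    Combines target-gene expression with target-pathway activation into a
    balanced efficiency score (BES) per targeted drug and patient, and ranks
    drugs by predicted benefit. Ships the validation machinery used to judge
    such scores against clinical outcomes: RECIST response dichotomization,
    rank-based ROC AUC, Kaplan-Meier curves, log-rank tests, Cox proportional
    hazards models, median-split prognostic screens over genes or pathways, and
    a random permutation test for multi-dataset overlap significance. A
    synthetic-cohort generator with planted pathway effects and outcome links
    supports end-to-end parameter-recovery testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
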