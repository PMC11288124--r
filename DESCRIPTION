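Package: fragstack
Title: cfDNA Fragmentomics Feature Extraction and Stacked Ensemble Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for plasma cell-free DNA (cfDNA) fragmentomics:
    genome coordinate frames (chromosome arms, fixed-width bins), fragment
    interval input/output with depth-standardising down-sampling, three
    genome-wide feature extractors (1-Mb copy-number log2 ratios with HMM
    segmentation and a tumor-fraction estimate; chromosome-arm fragment size
    distributions; nucleosome-footprint composite coverage around
    transcription-factor binding sites), a two-tier stacked ensemble
    classifier with specificity-targeted threshold calibration, and the
    evaluation statistics used in liquid-biopsy studies (bootstrap AUC
    confidence intervals, Wilson and Clopper-Pearson binomial intervals,
    positive percent agreement, Jonckheere-Terpstra trend test,
    differential-feature selection, hypergeometric enrichment, and
    limit-of-detection estimation). A synthetic plasma cohort generator makes
    the whole pipeline testable end-to-end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    xgboost,
    ranger,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
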