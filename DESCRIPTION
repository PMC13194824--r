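Package: cfFragSig
Title: Cell-Free DNA Fragmentomics Features and Ensemble Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extraction of copy-number (CNV), fragment-size-distribution (FSD)
    and promoter-fragmentation-entropy (PFE) features from fragment-level
    plasma whole-genome sequencing data, an out-of-fold-ranked ensemble
    classifier producing a cancer risk score, a diagnostic and calibration
    evaluation suite, and a sequencing-depth stability analysis for the
    entropy features. Ships a synthetic cfDNA cohort generator on a scaled
    genome so the full pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    data.table,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
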