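Package: vtpred
Title: Vesicular Transport Protein Prediction from PSSM Evolutionary Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies vesicular transport proteins from PSI-BLAST
    position-specific scoring matrices (PSSMs). Implements the AATP
    (amino-acid composition + transition probability composition) and
    CSP-SegPseP-SegACP (segmented pseudo-PSSM, segmented autocovariance
    transformation and consensus-sequence) feature encoders, edited
    nearest-neighbours and related resampling for class imbalance with
    leakage-free cross-validation, Max-Relevance-Max-Distance (MRMD)
    feature ranking with link-analysis rank aggregation, and a
    gradient-boosted classifier with a confusion-matrix metric suite.
    Includes a synthetic PSSM generator so the whole pipeline is testable
    without external sequence databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
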