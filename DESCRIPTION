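Package: trtkit
Title: Prediction of Tumor-Reactive T Cell Clonotypes from Paired
    scRNA-seq/scTCR-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Antigen-agnostic prediction of tumor-reactive T cell (TRT)
    clonotypes from paired single-cell RNA and TCR sequencing. Implements
    gene-signature and elastic-net logistic model families over log-normalized
    UMI counts, differential-expression signature derivation (single-cell
    Wilcoxon, pseudo-bulk quasi-likelihood F and moderated-t on clone-average
    profiles), clone-wise max-score aggregation with train-based scaling and
    accuracy-maximizing thresholds, leave-one-patient-out nested
    cross-validation with Matthews correlation coefficient model selection,
    y-randomization null calibration, immune repertoire richness/clonality
    metrics, CDR3 physicochemical featurization with a structural-avidity
    classifier and UPGMA TCR clustering, and the combinatorial candidate
    selection pipeline that returns one high-avidity tumor-reactive TCR per
    physicochemical cluster. A negative-binomial multi-patient cohort
    simulator with planted signatures and CDR3 sequence families supports
    end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    stats,
    utils,
    methods,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
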