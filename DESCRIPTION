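Package: emphaselearn
Title: Emphasis Learning: Feature Replication in Width for Tabular
    Biomedical Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification-improvement pipeline for multimodal tabular
    biomedical feature sets built around "emphasis learning": features are
    reduced by principal component analysis and then horizontally replicated
    (repeated in width) before training a linear maximum-margin classifier,
    with the replication factor searched until cross-validated performance
    stops improving.  Includes mean imputation, log/min-max/standardize
    rescaling fitted on training folds only, repeated stratified k-fold
    evaluation with the usual diagnostic metrics (accuracy, sensitivity,
    specificity, PPV, NPV, AUC), and a synthetic generator for cohort-like
    multimodal data (MRI/PET/CSF/MMSE/demographic blocks) with planted
    low-rank class structure and block-structured missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    kernlab,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
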