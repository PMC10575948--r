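Package: qsareval
Title: Rigorous Evaluation Methodology for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reusable pipeline for benchmarking molecular property
    prediction models on activity data: curation of SMILES/activity tables
    into deduplicated pIC50 datasets, fixed molecular representations
    (PhysChem, RDKit2D, MACCS, Morgan bit/count and atom-pair fingerprints)
    computed through RDKit, multi-seed random and balanced Bemis-Murcko
    scaffold splits, activity-cliff and edge-case annotation with
    cliff-stratified evaluation, a classification/regression metric suite
    (AUROC, AUPRC, PPV/NPV at Youden-J thresholds, RMSE, MAE, R2, Pearson r),
    Mann-Whitney pairwise model comparison with single-fold and triple-split
    win counting, and a synthetic molecule generator with planted scaffold
    structure, activity cliffs and near-cutoff edge cases so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    ranger,
    rlang,
    stats,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with the RDKit package, available as
    'python' on the PATH (override via options(qsareval.python = ...)).
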