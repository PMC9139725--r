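Package: PEFquant
Title: Volumetry and Hounsfield-Unit Classification of Pericardial
    Effusion on Chest CT
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-segmentation analysis of pericardial effusion (PEF) on
    chest CT: voxel-count volumetry from binary segmentation masks,
    range-filtered median Hounsfield-unit extraction for hemopericardium
    classification, rule-based detection and alerting, ROC-based
    threshold calibration (Youden and closest-top-left operating
    points), exact binomial confidence intervals, and an agreement
    statistics battery (Dice, Bland-Altman, ICC, Pearson r^2).  A
    synthetic thoracic phantom generator produces CT volumes with
    ground-truth effusion masks whose attenuation and volume statistics
    follow a clinical cohort, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
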