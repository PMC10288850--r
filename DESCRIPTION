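Package: actidel
Title: Delirium Detection from Bilateral Wrist Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A day-level pipeline for detecting delirium in hemiparetic
    stroke patients from bilateral wrist-actigraph recordings. Provides a
    synthetic cohort generator with circadian structure, paretic-arm
    activity suppression, shared care-event artifacts and device-removal
    gaps; epoch-table input/output with 13:00-anchored analysis days
    partitioned into morning, afternoon/evening and night windows;
    actigraph features (minutes at rest, dynamic-time-warping distances
    against within-patient control references, a median + 10 SD outlier
    filter); clinical covariate encoding; and patient-disjoint bootstrap
    evaluation of gradient-boosted tree classifiers with feature-set
    ablation, paired significance comparison and information-gain feature
    importance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    randomForest,
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
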