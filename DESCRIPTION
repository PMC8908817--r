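Package: henactivity
Title: Classifying Laying-Hen Activity Levels from Body-Worn Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for classifying the behaviour of individual laying hens
    into three activity levels (static, semi-dynamic, highly dynamic) from
    tri-axial accelerometer streams annotated in 0.5-second slots. Provides a
    synthetic session generator with a semi-Markov bout process, sensor and
    annotation file IO with clock synchronization, overlapping sliding-window
    segmentation with majority-vote labelling, a 31-dimensional statistical
    feature set, standardization, Pearson-correlation feature screening and
    PCA at a target explained variance, inverse-class-frequency
    misclassification penalties for severe class imbalance, and bagged-tree
    and random-forest ensembles evaluated by stratified k-fold
    cross-validation with confusion-matrix metrics and macro F1.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    ranger,
    stats,
    utils
Suggests:
    class,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
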