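Package: gliograde
Title: Interpretable Machine-Learning Grading of Gliomas from H&E Tile
    Images and Ki-67 Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated, interpretable platform for three-class glioma
    grading (WHO grades II, III, IV) from haematoxylin-and-eosin tile
    images and Ki-67 immunohistochemistry counts. Slides are partitioned
    into fixed-size tiles, the most cellular tiles are selected as regions
    of interest by watershed nucleus detection, and each case is summarised
    by a multiparametric battery: 24 visual features (nuclear morphology,
    staining, and spatial pattern), 171 sub-visual features (first-order
    intensity statistics and grey-level co-occurrence matrix texture), and
    the Ki-67 proliferative index. Random-forest importance ranking with
    backward feature elimination reduces the battery, four classifier
    families (random forest, gradient-boosted trees, support vector
    machine, neural network) are tuned and compared under repeated
    stratified hold-out, and per-case grading decisions are explained with
    a local linear surrogate (LIME-style) over perturbation samples. A
    synthetic cohort generator renders H&E-like tiles with grade-dependent
    nuclear density, size, pleomorphism, chromasia and clustering, plus
    matched Ki-67 counts, so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    nnet,
    png,
    randomForest,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
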