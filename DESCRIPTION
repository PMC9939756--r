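Package: SARFtex
Title: Self-Attention Random Forests for Multi-Scale Texture Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classification of grayscale texture images (histopathology,
    mammography and similar modalities) from pyramid gray-level
    co-occurrence-matrix (PGLCM) features. Images are decomposed into a
    Gaussian pyramid, Haralick statistics (contrast, correlation, energy,
    homogeneity) are computed from co-occurrence matrices at several
    offsets and fused across scales into a named feature vector. A shallow
    self-attention network learns per-feature importance weights that
    residually reweight the features before a random-forest classifier
    (the SARF composite). Includes out-of-bag permutation importance,
    grid-search tuning of forest depth and size, a full evaluation suite
    (confusion matrices, sensitivity/specificity/predictive rates,
    ROC/AUC with micro-averaging), image augmentation utilities for
    dataset balancing, and seeded synthetic texture and tabular
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'evaluation.R'
    'forest.R'
    'imaging.R'
    'pglcm.R'
    'pipeline.R'
    'san.R'
    'synthetic.R'
    'utils.R'
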