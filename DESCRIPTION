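Package: uavPheno
Title: UAV RGB Digital Phenotyping for Forage-Grass Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end digital phenotyping pipeline for single-plant forage
    breeding trials imaged with UAV RGB sensors. Simulates augmented block
    designs with genotype, harvest, block and residual variance structure and
    renders synthetic plot images whose projected area, canopy texture and
    greenness track latent biomass and vigor; segments plants with the
    modified excess-green index (MExG) and Otsu thresholding; extracts 171
    digital traits per plot (14 vegetation indices x 7 statistics, 12
    gray-level co-occurrence matrices x 6 Haralick descriptors, plant pixel
    count); prunes collinear features; associates digital with conventional
    traits via Pearson correlation with t tests; predicts traits with four
    regressors under repeated 4-fold cross-validation with Scott-Knott
    grouping; fits REML mixed models for augmented designs to obtain variance
    components, BLUPs/BLUEs, Wald and likelihood-ratio tests, broad-sense and
    Cullis heritabilities; and compares genotype rankings by breeding value
    through coincidence indices at several selection intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    randomForest,
    rpart,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    EBImage,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
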