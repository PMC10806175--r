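Package: RadCRT
Title: CT Radiomics Modeling of Chemoradiotherapy Response and Prognosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end CT radiomics pipeline for predicting tumor
    response to chemoradiotherapy and patient prognosis from volumetric
    CT with a delineated tumor volume of interest. Implements 3D
    undecimated wavelet decomposition into eight subband images,
    extraction of a 476-feature vector per case (shape, histogram and
    gray-level co-occurrence / run-length / size-zone texture features),
    ROC-based feature screening with Pearson-correlation redundancy
    grouping, five-classifier response modeling with DeLong AUC
    comparison and Youden cutoff derivation, and Kaplan-Meier / Cox
    survival stratification by prediction score. Includes a synthetic
    tumor-phantom cohort generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    e1071,
    glmnet,
    nnet,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Classification, Survival, FeatureExtraction
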