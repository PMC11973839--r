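Package: PolarSOS
Title: Interpretable Sum-of-Sigmoids Risk Models from Boosted-Stump
    Ensembles on Myocardial Perfusion Polar Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constructs interpretable sum-of-sigmoids classifiers for
    major adverse cardiovascular event (MACE) risk from ensembles of
    depth-one gradient-boosted tree models. Provides AHA 17-segment
    feature extraction from rest/stress/reserve myocardial perfusion
    polar maps, validated train/test splitting with undersampling
    stratification for imbalanced cohorts, score-curve averaging over
    boosted-stump ensembles with sigmoid shape-function fitting,
    confusion-matrix evaluation utilities, and a synthetic cohort
    generator so that every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    glmnet,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ensemble.R'
    'evaluation.R'
    'features.R'
    'geometry.R'
    'polarmap.R'
    'sos.R'
    'split.R'
    'synthetic.R'
    'utils.R'
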