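Package: cytoscaffold
Title: Reference-Guided Cell Type Annotation and Signaling-Based Survival
    Modeling for Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mass cytometry (CyTOF) single-cell protein
    expression data. Provides reference-guided automated cell type annotation
    via self-organizing-map clustering and cosine-similarity matching of
    cluster landmarks to annotated reference landmarks (a Scaffold-map
    adaptation), conditional-density resampled mutual information (DREMI)
    scoring of directed signaling protein pairs, per-cell-type feature
    engineering (median intensities and all ordered DREMI pairs), SMOTE
    class rebalancing, and repeated hold-out gradient-boosting models of
    short- versus long-term patient survival with feature-importance
    aggregation. A synthetic data generator with planted ground truth
    supports desk-scale validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'cytoscaffold-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'transform.R'
    'panels.R'
    'som.R'
    'landmarks.R'
    'annotate.R'
    'baselines.R'
    'protocol.R'
    'dremi.R'
    'features.R'
    'smote.R'
    'evaluation.R'
    'ml.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
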