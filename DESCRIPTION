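Package: caninecoping
Title: Digital Behavioral Assessment of Dog Coping Styles from Arena Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human-free pipeline for scoring dog coping styles in a
    Stranger Test arena from overhead tracking data. Provides a synthetic
    arena-cohort generator (stochastic dog trajectories, corrupted
    detections, three-rater ordinal scores, C-BARQ category profiles),
    detection-quality gating, gap filling and frame-rate standardization,
    a one-dimensional convolutional autoencoder that embeds each trial
    into a movement space, time-series k-means clustering with elbow-based
    model selection and outlier screening, inter-rater agreement statistics
    (free-marginal multirater kappa), Mann-Whitney comparison of C-BARQ
    categories between clusters, and a budgeted evolutionary pipeline
    search for expert-score classification and per-category C-BARQ
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo,
    glmnet,
    ranger,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
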