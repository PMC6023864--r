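Package: paleoniche
Title: Climatic-Niche Conservatism Tests via SDM Transferability and
    Environmental-Space Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combined geographical and environmental framework for testing
    climatic-niche conservatism across time slices. Species distribution
    models (polynomial logistic GLM, random forest, penalized log-linear
    Maxent-style density) are calibrated in one climate scenario and
    transferred to others with clamping, bootstrap and independent-presence
    AUC validation, and MESS/MoD extrapolation surfaces. A parallel
    environmental-space track builds kernel occupancy grids in a pooled
    two-axis PCA space and computes Schoener's D, niche equivalency and
    similarity randomization tests, expansion/stability/unfilling indices
    and centroid shifts. A synthetic climate-and-species generator with a
    known Gaussian niche truth makes every stage testable without external
    raster or occurrence databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
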