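Package: koastack
Title: Kepler-Optimised Stacking Ensembles with CARS Feature Selection for
    Multimodal Seed Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying crop seed varieties from fused Raman
    spectral and image-derived numeric features. Implements Savitzky-Golay
    smoothing and min-max scaling, competitive adaptive reweighted sampling
    (CARS) variable selection driven by partial least squares regression,
    the Kepler optimization algorithm (KOA) for hyperparameter tuning of
    six classifier families, and a two-layer stacking ensemble with
    out-of-fold meta-features and combinatorial meta-learner selection.
    Ships a synthetic multimodal data generator so the full pipeline can
    be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
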