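Package: ionochain
Title: Multi-Target Sequential Chaining for Ionome Prediction from
    Hyperspectral Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tissue element concentrations (the ionome) from
    hyperspectral reflectance spectra with single-target regression (STR)
    and a multi-target sequential chaining (MTSC) strategy, a
    forward-selection regressor chain that augments the spectral feature
    matrix with leakage-safe out-of-fold predictions of other element
    concentrations.  Includes the spectral preprocessing chain
    (per-band standardization, iterative Grubbs sample filtering,
    Savitzky-Golay smoothing, first-derivative transform), five tunable
    base learners behind a uniform fit/predict contract, cross-validated
    STR-versus-MTSC comparison with paired Wilcoxon signed-rank tests,
    descriptive ionome statistics, and a synthetic spectra/element
    simulator with known inter-element dependency structure for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    mixOmics,
    signal,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
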