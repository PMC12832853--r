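Package: plantarssl
Title: Balance Assessment from Wearable Plantar-Pressure Gait Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts Berg Balance Scale (BBS) scores from 16-channel
    plantar-pressure insole recordings. Implements gait-cycle detection by
    combined Fourier and autocorrelation analysis, extraction of a
    156-dimensional biomechanical feature vector (pressure peaks,
    pressure-time integrals, half-peak widths, centre-of-pressure
    displacement, bilateral symmetry indices), multi-model label-noise
    screening with a frequency consensus, two-step feature selection
    (correlation pruning followed by cross-validated LASSO), and a
    consistency-regularised semi-supervised linear regression trained with a
    composite supervised-plus-consistency loss. A synthetic gait generator
    with a known ground-truth balance latent and injectable label noise
    supports end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
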