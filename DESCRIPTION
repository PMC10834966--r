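Package: emgsynergy
Title: Muscle Synergy Extraction and Complexity Metrics for Running Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the modular analysis of multi-muscle surface
    electromyography (sEMG) recorded during treadmill running. Raw force and
    sEMG signals are turned into time-normalized gait-cycle tensors
    (Butterworth envelope extraction, 50 N touchdown/toe-off detection,
    200-point cycle grid); muscle synergies are extracted by Gaussian
    non-negative matrix factorization with multiplicative updates, best-of-5
    restarts and a linearity-pruning rule for the number of synergies; motor
    modules and motor primitives are described by linear metrics
    (co-contribution index, circular center of activity, full width at half
    maximum, half-maximum exceedance and overlap frequencies) and by nonlinear
    fractal metrics (Higuchi's fractal dimension, rescaled-range Hurst
    exponent); synergies are functionally classified by dual k-means
    clustering of primitives and modules. A synthetic-data generator produces
    cyclic sEMG with known modules, bump-shaped primitives, tunable noise and
    cycle-to-cycle persistence (fractional Gaussian noise) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
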