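Package: stiffsim
Title: Simulated Arm Motion and Visual Stiffness Perception Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a two-link planar arm driven by superimposed
    mechanical-impedance primitives (an oscillatory endpoint attractor plus a
    fixed-point joint attractor), extracts steady-state endpoint cycles,
    re-times them under constant-speed, inverse power-law and transplanted
    time-vector velocity profiles, computes a battery of path and temporal
    features (oblongness, enclosed area, mean curvature, joint relative
    phase, range of motion, RMS velocity/acceleration/jerk), generates
    synthetic Likert ratings that emulate blocked psychophysics experiments
    with quantization and central-tendency bias, and runs the per-subject
    regression analysis used to quantify how well observers track simulated
    joint stiffness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
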