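Package: sleepmanifold
Title: NREM Sleep Oscillation Coupling and Neural Manifold Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic multi-area sleep electrophysiology
    during long-term skill learning. Classifies NREM sleep from LFP band power,
    detects slow oscillations, sleep spindles and hippocampal sharp-wave
    ripples with filter/threshold detectors, quantifies cross-area event
    coupling against circular-permutation null models, tracks coupling and
    performance time courses across days (sigmoid, piecewise-linear and
    change-point fits, two-stage logistic staging), estimates low-dimensional
    neural manifolds with Gaussian-process factor analysis (trajectory
    fidelity, cross-day Procrustes alignment), measures sharp-wave-ripple
    locked reactivation of awake ensemble templates, and characterizes the
    prefrontal-motor communication subspace with canonical correlation
    analysis. Includes a synthetic-session generator with recorded ground
    truth so every stage is testable without chronic recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    vegan,
    rhdf5,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
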