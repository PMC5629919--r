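Package: rtnirs
Title: Real-Time fNIRS Signal Processing, Incremental GLM Analysis,
    Decoding, and Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A streaming analysis engine for functional near-infrared
    spectroscopy (fNIRS). Converts raw dual-wavelength light intensities to
    oxygenated and deoxygenated hemoglobin concentration changes via the
    modified Beer-Lambert law with a streaming baseline, applies strictly
    causal preprocessing (incremental detrending, moving-average smoothing,
    IIR filter banks, correlation-based motion correction), fits an
    incremental recursive least-squares general linear model whose beta
    estimates equal batch ordinary least squares at every sample, estimates
    single-trial responses for multivariate pattern classification with a
    linear support vector machine (leave-one-run-out cross-validation and a
    permutation test), and computes thermometer-style neurofeedback values
    relative to hemodynamically shifted baselines. A forward simulator
    generates synthetic sessions, from ground-truth hemodynamics down to raw
    intensities, so the complete pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
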