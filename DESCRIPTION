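Package: frpmap
Title: Flexion-Relaxation Analysis of High-Density Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the flexion relaxation phenomenon (FRP) of the
    lumbar paraspinal muscles from high-density surface electromyography
    (HDEMG). Implements electrode-grid geometry and monopolar-to-bipolar
    derivation, channel quality screening, zero-phase band-pass filtering and
    envelope extraction, electrogoniometer-based phase segmentation of trunk
    flexion trials, per-channel detection of the EMG offset (FRP onset) by
    baseline thresholding, topographic onset mapping, epoch-wise RMS amplitude
    profiling normalised to the extension-phase peak, and mixed-effects
    smoothing-spline ANOVA with Bayesian confidence intervals for group
    inference on onset maps and amplitude curves. A synthetic-cohort generator
    with known ground truth supports end-to-end validation and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
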