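Package: baroresp
Title: Cardiorespiratory Variability and Baroreflex Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spectral analysis of cardiovascular and respiratory
    variability from multichannel physiological recordings (one-lead ECG,
    continuous finger arterial pressure, uncalibrated respiratory volume).
    Implements R-peak detection with parabolic refinement, beat-by-beat
    R-R interval and systolic pressure series extraction, breath-by-breath
    respiratory volume decomposition, Welch power spectra with broadband
    smoothing and VLF/LF/HF band powers, magnitude-squared coherence and
    transfer-function baroreflex sensitivity, amplitude-adjusted Fourier
    surrogate significance testing, and the group/condition comparison
    layer (per-frequency t statistics on transformed spectra,
    repeated-measures ANOVA with trend-gated LSD contrasts and a rank
    fallback). A seeded synthetic-data generator emulates the assumed
    statistical structure of the signals so the whole chain is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
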