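Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Multiwavelength Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating systolic, diastolic and mean arterial blood
    pressure from a single photoplethysmogram (PPG) via heart rate and the
    modified normalized pulse volume (mNPV, the AC/DC ratio of the pulse
    waveform). Implements beat detection with outlier-beat removal, per-window
    averaging of heart rate and mNPV, the baseline-referenced log-linear
    regression model linking log blood-pressure change to log changes in heart
    rate and mNPV, exponential back-transformation to millimetres of mercury,
    and an evaluation layer: per-wavelength coefficients of determination,
    one-way repeated-measures ANOVA with Tukey HSD across wavelengths,
    Bland-Altman agreement statistics, paired t tests, geometric-mean
    regression and Shapiro-Wilk residual checks. A seeded synthetic-data
    generator emulates multiwavelength finger-PPG sessions (four LED channels,
    rest and mental-stress conditions) with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
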