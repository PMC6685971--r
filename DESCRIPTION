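Package: awakeosa
Title: Screening Obstructive Sleep Apnea from Tracheal Breathing Sounds
    Recorded During Wakefulness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the AWakeOSA screening procedure for obstructive
    sleep apnea (OSA) from a few minutes of tracheal breathing sounds
    recorded during wakefulness. Recordings of deliberate nose and mouth
    breathing are segmented into inspiratory and expiratory phases;
    spectral (Welch), bispectral (indirect third-cumulant estimator) and
    fractal (Katz, Higuchi, Hurst) features are extracted over
    discriminative frequency bands; features are reduced by significance,
    robustness scoring, redundancy removal and effect size; random-forest
    classifiers are trained with out-of-bag validation inside
    anthropometric subgroups (age, sex, BMI, neck circumference,
    Mallampati score); and their votes are fused with a
    sensitivity/specificity-weighted average into a final decision in
    [-1, 1]. A synthetic-cohort generator produces anthropometrics
    correlated with the apnea/hypopnea index and breathing-sound audio
    carrying the group contrasts the method assumes, so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    ranger,
    e1071,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
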