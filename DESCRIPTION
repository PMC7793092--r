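Package: hypnoscore
Title: Sleep Scoring from Wrist Actigraphy and Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-by-epoch sleep scoring from wrist-actigraphy activity
    counts fused with heart rate variability (HRV) metrics derived from
    RR-interval series. Implements per-epoch computation of 17 time- and
    frequency-domain HRV metrics over configurable trailing windows, a
    convolutional-LSTM classifier of wake/NREM/REM trained from scratch,
    the classic UCSD weighted-window actigraphy comparator, SpO2-based
    record-bound detection, derivation of standard sleep parameters
    (TST, SE, SOL, WASO, REM/NREM minutes), and device-versus-reference
    evaluation statistics (epoch-by-epoch agreement, Cohen's kappa,
    Bland-Altman method comparison). Includes a seeded synthetic cohort
    simulator producing stage-conditioned activity counts and RR series
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
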