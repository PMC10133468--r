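Package: tonofit
Title: Imaging-Based Tonotopic Fitting and Daily-Randomized Trial Tools for Cochlear Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for imaging-based frequency fitting of cochlear implants and
    for the analysis of daily-randomized within-patient crossover trials.
    Maps electrode insertion geometry to tonotopic place frequencies with the
    Greenwood function, builds and validates frequency allocation tables (FATs)
    with a low-frequency rule set and a virtual (phantom) channel, quantifies
    frequency-to-place mismatch in octaves, generates constrained daily wearing
    schedules with compliance auditing, and analyses longitudinal speech
    outcomes via interpolated learning curves (Begin, End, AUC, learning rate),
    exact Wilcoxon signed-rank comparisons with Holm-Bonferroni correction,
    categorical loudness-scaling AUCs, and adaptive staircase simulation. A
    synthetic cohort generator emulates anatomy, schedules, diaries and
    longitudinal outcomes so the full pipeline runs without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
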