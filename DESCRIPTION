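Package: beatmem
Title: Auditory Beat Stimulation and Memory-Related Single-Unit Firing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-aligned analysis of human medial temporal lobe single-unit
    recordings during auditory beat stimulation (binaural versus monaural 5 Hz
    beats) in an associative recognition task. Provides windowed firing-rate
    extraction, a 2 Hz inclusion filter, selection of beat-responsive units by
    rank-sum tests with Bonferroni correction, normalized firing-rate difference
    statistics, population-level binomial, overlap and chi-square tests,
    correlations between beat-related and memory-related firing-rate
    differences (including the pre-stimulus baseline-shift analyses and an
    exploratory homeostatic correlation scheme), behavioral summaries with
    repeated-measures ANOVA, and a seeded Poisson spike-train simulator
    implementing a homeostatic baseline-shift model so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
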