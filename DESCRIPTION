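Package: micqi
Title: Performance-Indicator Quality Control for Regional Medical Major-Incident Command
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Applies an 11-item time-standard performance-indicator rubric to
    decision logs from regional medical command and control at major
    incidents. Provides a JSON-lines/CSV incident-log format with readers and
    writers, the 0/1/2 scoring engine, cohort applicability and
    documentation-completeness filters with flow accounting, descriptive
    summaries, a randomized-complete-block two-way ANOVA with Tukey HSD
    pairwise comparisons and a compact line-grouping display, and a seeded
    synthetic cohort generator with presets calibrated to published incident
    mixes and indicator mean scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
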