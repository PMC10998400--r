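Package: randelphi
Title: Analysis Pipeline for RAND-Modified Delphi Questionnaire Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative stages of a RAND-modified Delphi
    study that develops and content-validates a questionnaire with an
    expert panel: ingestion and validation of panelist Likert ratings and
    top-k question rankings, per-item median and tertile statistics, the
    points-based prioritization (top) percentage, preselection and
    consensus classification with a green/orange/red triage, personalized
    per-expert feedback reports, auditable decision ledgers that transform
    one questionnaire version into the next, and a seeded synthetic-panel
    generator for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
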