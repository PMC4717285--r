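Package: trialtalk
Title: Conversational Faceted Search over Clinical-Trial Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conversational search engine for clinical-trial registries aimed
    at users with low health literacy. Trials are retrieved by faceted
    eligibility filtering over indexed criteria (age, sex, cancer type,
    location, trial type, phase, investigational drug) and ranked by three
    subjective attributes (pain, invasiveness, time burden) predicted from the
    trial free text by ID3 decision trees over boolean word-occurrence
    features. A scripted multiple-choice dialog agent drives the interview,
    search, staged trial presentation, dictionary look-ups, bookmarking and
    query refinement. The package ships seeded synthetic-data generators for
    trial corpora with planted word-label associations and simulated two-arm
    trial outcomes, plus the nonparametric evaluation statistics (uncorrected
    Pearson chi-square on 2x2 tables, Mann-Whitney U with tie correction and
    small-sample exact enumeration) used to analyse such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
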