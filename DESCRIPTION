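Package: semiology
Title: Hierarchical Encoding and Rule-Based Extrapolation of Seizure Semiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Standardized, hierarchical encoding of seizure-video semiology
    (episode, event, behavior with integer-second timing) against a controlled
    vocabulary of eleven ictal event types, together with four semiologic
    extrapolation rule functions (focal-onset features, psychogenic
    non-epileptic seizure features, Jacksonian march detection, SUDEP risk
    factors), chronological report and timeline rendering, a seeded generator
    of labeled synthetic episodes, and cohort evaluation statistics with exact
    (Clopper-Pearson) binomial confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
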