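Package: songshift
Title: Hierarchical Bootstrap Analysis of Vocal Pitch Adaptation in Songbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis machinery for headphones pitch-shift experiments in
    Bengalese finches: semitone pitch metrics against per-syllable baselines,
    a three-level (bird / syllable / iteration) hierarchical bootstrap for
    nested behavioral data, posterior-probability hypothesis tests on
    bootstrap distributions with Bonferroni-corrected two-way decisions,
    nested random-intercept linear mixed model validation, an optical-density
    lesion-extent metric for 6-OHDA lesions of Area X, and a synthetic cohort
    generator with known ground truth for calibration and parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
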