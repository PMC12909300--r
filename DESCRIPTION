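Package: bwdyn
Title: Body-Weight Dynamics: State Segmentation, Homeostasis Traits, and
    Survival Association for Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments longitudinal body-weight trajectories into growth,
    steady, and decline states with a constrained lag-1 autoregressive
    hidden Markov model, derives per-animal homeostasis and
    stress-adaptation traits from the decoded state posteriors, associates
    age-binned traits with mortality through a time-varying Cox
    proportional-hazards model, and provides clustered false-discovery-rate
    thresholds and founder-allele-pattern grouping for genetic mapping in
    multiparental mouse populations. Includes a synthetic-cohort generator
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
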