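Package: enrichjm
Title: Adaptive Enrichment Trial Designs Using Joint Models for
    Longitudinal Biomarkers and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation of two-stage adaptive enrichment trials
    whose analysis is based on a joint model for a longitudinal biomarker and
    a time-to-event endpoint. Treatment effects are estimated by a multi-stage
    conditional-score method that is robust to biomarker measurement error;
    subgroup selection uses a threshold rule on interim Z-statistics and
    hypothesis testing uses an error-spending group-sequential boundary.
    Includes a trial simulator calibrated to a metastatic breast cancer
    setting (linear circulating tumour DNA trajectories with random effects
    and a piecewise-constant baseline hazard), comparator Cox analyses with
    and without the biomarker as a time-varying covariate, an event-based
    information calibration for planning the required numbers of events, and
    Monte-Carlo evaluation of operating characteristics (familywise error
    rate, power, selection probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
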