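Package: mrfscore
Title: Medication-Related Fall Screening and Scoring with Delphi Consensus Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the Medication-Related Fall (MRF) screening and
    scoring tool: a tiered catalog of fall-risk-increasing medication
    classes (high = 3 points, moderate = 2, low = 1) with drug-name
    normalisation, per-patient summation scoring under the highest-score
    rule, and medication-review referral flagging. Also provides the
    Delphi consensus engine used to content-validate such tools:
    per-item Likert statistics (agreement percentage, median, quartiles),
    percentile-based retain/modify/exclude decision rules with full rule
    traces, multi-round orchestration with panel feedback summaries, panel
    demographics summaries, and seeded generators for synthetic panel
    response matrices and patient medication lists. All user-facing
    functions take data frames and return tibbles; results carry broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods. A thin
    command-line interface (exec/mrf) exposes scoring, catalog validation,
    Delphi analysis and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
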