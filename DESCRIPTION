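Package: milesurv
Title: Milestone Survival and Restricted Mean Survival Time Surrogacy for
    Immunotherapy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level evaluation of surrogate endpoints for overall
    survival in randomized immunotherapy trials with non-proportional
    hazards, as arises in first-line treatment of extensive-stage small
    cell lung cancer. Computes Kaplan-Meier curves, milestone survival
    rates and restricted mean survival times (RMST) from subject-level
    records or from digitized survival-curve coordinates, assembles
    experimental-versus-control effect measures (hazard ratios, relative
    risks, milestone-rate and RMST ratios), and quantifies surrogacy by
    Spearman rank correlation and sample-size-weighted least-squares
    regression of the log hazard ratio for overall survival on the log
    surrogate effect. Includes a piecewise-exponential trial simulator
    with delayed treatment effect, cure fraction, censoring and
    correlated response outcomes, plus a digitization emulator, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
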