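Package: caaprior
Title: Priority Scoring and Waiting-List Simulation for Coronary Angiography Referrals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exercising a multi-criteria prioritisation
    framework for patients awaiting elective coronary artery angiography.
    Derives factor weights from expert pairwise-comparison matrices by the
    analytic hierarchy process (principal eigenvector with Saaty consistency
    diagnostics and geometric-mean aggregation across experts), implements the
    modified-Delphi factor-selection arithmetic (median bands on a 9-point
    Likert scale and an agreement-rate stopping rule), computes each patient's
    100-point weighted priority score with three urgency tiers and maximum-wait
    targets, and runs a discrete-event waiting-list simulator that compares the
    priority policy against first-come-first-served scheduling on a common
    synthetic referral stream. Includes CSV/JSON readers and writers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
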