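Package: treestrat
Title: Survival-Tree Risk Stratification for Heart Failure Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives and validates decision-tree style risk stratification
    for right-censored survival cohorts, as used for patients with severe
    secondary mitral regurgitation across the heart failure spectrum. The
    toolchain covers univariate Cox screening, bootstrap stepwise Cox
    stability selection within clinical, echocardiographic and laboratory
    variable domains, conditional-inference survival trees grown with
    multiplicity-adjusted permutation log-rank tests, per-subgroup
    Kaplan-Meier and Cox hazard-ratio reporting, and internal plus temporal
    validation. A calibrated synthetic cohort generator (piecewise
    exponential leaf hazards on a known truth tree with staggered entry and
    right censoring) makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
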