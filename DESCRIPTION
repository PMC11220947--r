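Package: nedose
Title: Norepinephrine Dose Reporting Conventions and Mortality Prediction
    in Septic Shock
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how the convention used to report
    norepinephrine doses (base molecule versus tartrate, bitartrate or
    hydrochloride salt) distorts mortality prediction in septic shock.
    Provides salt/base dose conversion and norepinephrine-equivalent
    scoring, a synthetic ICU cohort generator with realistic infusion
    event streams, Sepsis-3 cohort screening with an exclusion ledger,
    stability-filtered peak-dose extraction, logistic dose-response
    modelling per reporting convention with predicted mortality at
    common severity thresholds, and an end-to-end reporting pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
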