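Package: aomcohort
Title: Incidence and Trend Analysis of Acute Otitis Media in Pediatric
    Primary-Care Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the burden of acute otitis media (AOM)
    from a pediatric primary-care visit stream: identification of
    AOM-related visits from ICD-9-CM codes and free-text diagnoses,
    grouping of visits into episodes with a 14-day gap rule,
    classification of episodes as simple or recurrent under a windowed
    recurrence definition, person-time accrual by calendar year and age
    band, annual and mean annual incidence rates per 1000 person-years
    with Poisson normal-approximation confidence intervals, Mann-Kendall
    monotonic-trend tests, and a two-period segmented negative-binomial
    interrupted time series. A synthetic cohort generator with
    age-band-specific rates, per-child frailty, follow-up visit
    clustering, and staggered enrollment supports testing and parameter
    recovery when real registry data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
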