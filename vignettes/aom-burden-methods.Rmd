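---
title: "Methods: estimating the burden of acute otitis media from a primary-care visit stream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the burden of acute otitis media from a primary-care visit stream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aomcohort)
```

## The problem

Acute otitis media (AOM) is among the most common infections of early
childhood. Pediatric primary-care databases record it as a stream of
visits, each carrying an ICD-9-CM diagnosis code and/or a free-text
diagnosis. Turning that stream into an epidemiological burden estimate
requires a chain of decisions: which visits count as AOM, how repeated
visits for the same infection are collapsed into one *episode*, which
episodes are *recurrent* disease rather than independent infections, how
person-time at risk is accrued, and how annual incidence rates and their
time trends are estimated. `aomcohort` implements that chain as a tested,
reusable pipeline, together with a synthetic cohort generator so every
stage can be exercised and validated without access to a real registry.

## Case identification

A visit is AOM-related when any of its ICD-9-CM codes (primary or
secondary position) starts with a configured rubric prefix — by default
`382`, so `382`, `382.0`, `382.00`, ... match and `381.x` or `038.2` do
not — **or** when its free-text diagnosis matches the otitis text search:
the patterns `oti*`, `*oti*`, `om*`, `*om*`. Two design choices deserve
comment:

* **Token anchoring.** The four patterns are only distinguishable if
  anchoring is relative to word starts; matched against the raw string
  they all collapse into "contains `om` or `oti` somewhere". We therefore
  split the normalised text on whitespace and let prefix patterns anchor
  at token starts while substring patterns match anywhere within a token.
  Matching is case-insensitive by default, since clinical free text has
  inconsistent casing.
* **Exclusion list.** In registry studies, free-text matches are weeded
  manually by clinical experts. Manual review is not reproducible, so the
  package replaces it with an explicit exclusion list of exact normalised
  strings (one per line, `#` comments allowed); a match that equals an
  excluded string is rejected. The bundled fixture contains common
  Italian false positives of the `*om*` pattern such as "vomito". The
  list is a configurable stand-in, not a claim about any expert's
  criteria.

## Episode construction

An AOM episode comprises one or more AOM-related visits; visits close in
time are follow-ups of the same infection. The operative rule is the
14-day gap: a gap of more than `gap_days` (default 14) between AOM visits
starts a new episode. Two readings of this rule exist and they disagree
for chains of three or more visits:

* `rolling` (the default): the gap is measured from the *previous* visit,
  so visits on days 0, 10, 20 form one episode;
* `anchor_to_first`: every visit must fall within 14 days of the
  episode's *first* visit, so the day-20 visit above starts a new episode.

We default to `rolling` because the consecutive-gap formulation is the
operative definition of a new episode start; the anchor reading remains
available as a configuration option. Same-day duplicate AOM visits are
merged before grouping, to avoid counting administrative re-entries.

Episodes take their calendar year from the onset date (episodes crossing
New Year belong to the year they began), and their age band from exact
birthday arithmetic: `<2` up to the day before the second birthday,
`2-4` from the second to the day before the fifth, `5-14` from the fifth
to the day before the fifteenth. Onsets on or after the fifteenth
birthday leave the study population and are dropped.

### Eligibility

Children contribute episodes only if registered at least 6 months before
their first (index) episode — waived under 1 year of age — and still
registered at least 12 months after it, and if they have at least 2
distinct visit dates. Month windows are fixed day counts (183 and 365
days) so the filters are calendar-independent. Three open points were
resolved as follows, each behind a configuration knob:

* The distinct-visit minimum counts visits of *any* cause, reading the
  rule as a data-quality filter on under-observed children.
* The 12-month post-index requirement is about continued registration,
  so it is waived for children whose follow-up is administratively
  censored at the study end: a child whose index episode falls in the
  final study year but who is still registered at close-out is retained.
  Without this waiver, every first episode near close-out would be
  deleted from the numerator while the child's person-time stayed in the
  denominator, biasing final-year rates downward by design.
* Excluded children keep their person-time in the denominators (the
  published denominator is the full cohort, while a smaller subset
  contributes episodes); removing it as well is available as an option.

## Recurrence

An episode is *recurrent* when the child has at least 3 episode onsets
within 6 months (183 days) or at least 4 within 12 months (365 days) —
windows closed at the current onset, open on the left — **and** at least
one earlier onset lies in the preceding 6 months, evaluated strictly
before the current onset (otherwise the condition would be vacuous
whenever the short-window count fires). All other episodes, including
every child's first, are *simple*.

The definition is silent on which episodes of a qualifying cluster carry
the label. The default (`label_mode = "completing"`) labels the episode
that completes a qualifying window, which keeps classification causal
and streamable; `label_mode = "cluster"` back-labels the whole qualifying
window. The choice affects the recurrent-AOM numerator magnitudes but
not the overall episode counts.

## Person-time and rates

Each child's observation interval runs from the latest of registration,
study start, and birth to the earliest of deregistration, study end, and
the day before the fifteenth birthday. The interval is split at each
1 January and at the band-edge birthdays; every fragment's inclusive day
count lands in exactly one (year, age band) cell. All arithmetic is at
day resolution, and person-years are days/365.25 — a fixed convention
that avoids leap-year drift and makes the additivity of fragments exact
and testable.

The incidence rate is `1000 * events / person_years`, and its 95%
confidence interval uses the Poisson normal approximation with
half-width `1.96 * sqrt(events) / person_years * 1000`, floored at zero.
This closed form reproduces, after half-up integer rounding, every
published annual and pooled rate and interval of the Veneto reference
series bundled as `veneto_annual_ir()` / `veneto_mean_ir()` — the
package's test suite asserts all 38 of them. Simple and recurrent
episodes share the full person-time denominator, so their rates add to
the overall rate.

## Trend analysis

Two complementary analyses run per series (overall, each age band,
simple, recurrent):

* **Mann–Kendall test.** `S` is the sum of signs of all pairwise
  differences; its variance uses the standard tie correction; `Z =
  S/sqrt(Var S)` with **no** continuity correction, two-sided normal
  p-value. The no-correction choice is deliberate: on the bundled
  reference series it yields p = 0.0065 (2–4 years) and p = 0.0478
  (<2 years), whereas the continuity-corrected variant gives 0.0094 and
  0.0635 — only the uncorrected statistic matches the published values.
* **Segmented negative-binomial ITS.** Annual stratified counts (year ×
  age band × sex, optionally risk flags) are modelled as
  `log mu = b0 + b1*t + b2*post + b3*(year - break)*post + covariates +
  log(person_years)`, with `t` the years since study start and `post`
  the late-period indicator (break at 2014, the first late year).
  `exp(b1)` is the early-period annual rate ratio, `exp(b2)` the
  immediate level change, `exp(b1+b3)` the late-period annual rate ratio
  (standard error by the delta method). Dispersion is estimated by full
  maximum likelihood (`MASS::glm.nb`, convergence tolerance 1e-8, up to
  100 iterations). When the data are equidispersed the dispersion MLE
  sits on the zero boundary and the shape parameter diverges; the fit
  then degenerates to its exact Poisson limit, which the package fits
  directly, reports with dispersion 0, and flags in the convergence
  report. Covariates enter additively on the log scale on stratified
  counts — the faithful aggregate analogue of child-level adjustment
  when only aggregate series are available.

With eight annual points per series, autocorrelation-robust inference
(seasonal ARIMA, Newey–West) is out of scope, as is any claim to
reproduce the original study's exact ITS coefficients, which would
require the individual-level registry data; parameter-recovery
simulations substitute (below).

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes. Its defaults are the study conditions, chosen once:

* **Demographics and enrollment.** Births uniform over the 23-year span
  that makes a child younger than 15 at some point in 2010–2017; male
  fraction 0.512; preterm and comorbidity flags at 5% and 2%.
  Registration follows birth after an exponential delay with hazard
  12/year (mean ≈ 1 month), matching a registry in which pediatricians
  enroll children essentially at birth — so children born before the
  study carry long pre-study registration and the 6-month pre-index
  filter bites only for genuinely late entrants. Deregistration is
  exponential with hazard 0.03/year, capped at study end.
* **Episode process.** Per-child non-homogeneous Poisson process,
  piecewise constant over (calendar year × age band) segments, thinned to
  the enrollment interval. Base rates 180/200/48 per 1000 person-years
  for `<2`/`2-4`/`5-14`, an annual rate ratio of 0.94 in both the early
  and late periods, and a per-child log-normal frailty (sd 0.8 on the
  log scale, mean 1) that induces recurrence-prone children. Frailty is
  a deliberate simplification of recurrence dynamics — it creates
  heavy-tailed per-child episode counts without modelling self-exciting
  within-child contagion.
* **Visits.** Each episode emits one index visit (ICD-9-coded with
  probability 0.6, otherwise free text from a small true-positive
  vocabulary) and, with probability 0.5, 1–2 follow-up visits within 14
  days, clipped to the follow-up window — so episodes carry 1–3 visits,
  a choice documented here because no within-episode visit-count
  distribution is available to calibrate against. False-positive visits
  (free text matching `*om*` but on the exclusion list) occur at 20 per
  1000 person-years, and routine background visits with non-matching
  diagnoses at 4 per person-year; the latter keep genuinely observed
  children above the 2-distinct-visits data-quality filter, as
  well-child care does in reality.

What the generator does **not** emulate: seasonality of viral
co-circulation, hospital/ER contacts, prescriptions, and the specific
comorbid conditions behind the opaque flags. Passing recovery tests on
synthetic data therefore shows the pipeline's internal consistency under
the assumed structure — not that real registry data meet those
assumptions.

`ground_truth()` returns the simulated onsets and true labels, enabling
the recovery tests: with follow-up visits and false positives disabled,
the detected episodes equal the gap-rule grouping of the true onsets
exactly; at 5,000 children with frailty 0 and a flat trend, the
pipeline's band-level rate estimates fall within Monte-Carlo error
(3 standard errors) of the configured 180/200/48.

## Numerical and testing choices

* Dates are base `Date` objects; Feb-29 anniversaries roll forward to
   1 March in non-leap years, deterministically.
* Reported rates round half-up to integers (`format_incidence()`);
  internal values keep full precision.
* All generator randomness flows from the single `seed` in the
  parameters; identical parameters give byte-identical tables.
* Problem sizes in the test suite were chosen to make Monte-Carlo checks
  informative while keeping the default run quick: 1,000 random cases for
  each property oracle (episode grouping, recurrence windows, person-time
  additivity), a 5,000-child cohort for rate recovery, and 100 replicates
  at registry-scale person-years (~50,000/year) for ITS coverage and
  power.
* The ITS recovery checks use stratified counts simulated directly from
  the segmented model at those registry-scale denominators: the
  early-trend CI covers the true 0.94 annual rate ratio in ≥90/100
  replicates, and an injected 8% level drop at the break is detected
  (p < 0.05) in ≥80/100.

## Known limitations

* The exclusion list is a fixed vocabulary; real free-text review is
  adaptive and multilingual clinical text is messier than the fixture.
* The frailty model ignores age-dependence of recurrence propensity.
* The ITS operates on aggregate stratified counts; child-level covariate
  adjustment on individual histories is out of scope.
* Rate comparisons between simple and recurrent subsets inherit the
  `label_mode` choice; cluster-mode numerators can differ materially in
  high-frailty populations.
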