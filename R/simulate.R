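#' Parameters for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated pediatric primary-care
#' cohort: age-band-specific AOM episode rates, a multiplicative annual
#' rate trend split into early/late periods, per-child log-normal frailty
#' (inducing recurrence-prone children), follow-up visits clustered within
#' 14 days of an episode onset, false-positive free-text records, routine
#' background visits, and staggered enrollment/dropout.
#'
#' Episode onsets are drawn from a per-child non-homogeneous Poisson
#' process with piecewise-constant intensity by age band and calendar
#' year, thinned to the child's enrollment interval. The year-`y` rate in
#' band `b` is `base_rates[b] / 1000` per person-year times
#' `multiplier(y)` times the child's frailty, with
#' `multiplier(y) = early^min(t, tb) * late^max(0, t - tb)` where
#' `t = y - start_year` and `tb` is the last early-period year index, so
#' the early and late annual rate ratios apply on their own segments.
#'
#' @param n_children number of children to simulate.
#' @param study_start,study_end study window (defaults 2010-01-01 to
#'   2017-12-31).
#' @param base_rates named numeric vector of AOM episode rates per 1000
#'   person-years; names must exactly cover the age-band labels implied by
#'   `edges` (default `c("<2" = 180, "2-4" = 200, "5-14" = 48)`).
#' @param annual_rate_multiplier named vector `c(early = , late = )` of
#'   per-year multiplicative rate ratios in the two periods (default 0.94
#'   in both, a gradual decline).
#' @param breakpoint_year first year of the late period (default 2014).
#' @param followup_visit_prob probability that an episode generates 1-2
#'   follow-up visits within 14 days of onset (default 0.5).
#' @param recurrence_frailty_sd standard deviation (log scale) of the
#'   per-child log-normal rate multiplier, mean-1 parameterisation
#'   (default 0.8; 0 disables heterogeneity).
#' @param false_positive_text_rate rate per 1000 person-years of non-AOM
#'   visits whose free text matches the otitis search patterns but is on
#'   the exclusion list (default 20).
#' @param background_visit_rate rate per person-year of routine visits with
#'   non-matching diagnoses (default 4; keeps genuinely observed children
#'   above data-quality visit-count filters, as real well-child care does).
#' @param enrollment_hazard per-year hazard of registration after birth
#'   (default 12, i.e. mean delay one month; staggered enrollment).
#' @param dropout_hazard per-year hazard of deregistration after
#'   enrollment (default 0.03).
#' @param sex_ratio probability of male sex (default 0.512).
#' @param preterm_prob,comorbidity_prob risk-flag prevalences (defaults
#'   0.05 and 0.02).
#' @param icd9_coded_prob probability that an AOM visit carries an ICD-9
#'   code rather than free text only (default 0.6).
#' @param edges age-band edges in years (default [age_band_edges()]).
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_children,
                          study_start = "2010-01-01",
                          study_end = "2017-12-31",
                          base_rates = c("<2" = 180, "2-4" = 200,
                                         "5-14" = 48),
                          annual_rate_multiplier = c(early = 0.94,
                                                     late = 0.94),
                          breakpoint_year = 2014L,
                          followup_visit_prob = 0.5,
                          recurrence_frailty_sd = 0.8,
                          false_positive_text_rate = 20,
                          background_visit_rate = 4,
                          enrollment_hazard = 12,
                          dropout_hazard = 0.03,
                          sex_ratio = 0.512,
                          preterm_prob = 0.05,
                          comorbidity_prob = 0.02,
                          icd9_coded_prob = 0.6,
                          edges = age_band_edges(),
                          seed = 1L) {
  if (!is.numeric(n_children) || length(n_children) != 1 ||
      is.na(n_children) || n_children < 0 || n_children != round(n_children)) {
    abort("`n_children` must be a single non-negative integer")
  }
  study_start <- as_date_strict(study_start, "study_start")
  study_end <- as_date_strict(study_end, "study_end")
  if (!study_start < study_end) abort("`study_start` must precede `study_end`")
  labs <- age_band_labels(edges)
  if (!setequal(names(base_rates), labs)) {
    abort(sprintf("`base_rates` names must exactly cover the age bands: %s",
                  paste(labs, collapse = ", ")))
  }
  stopifnot_nonneg(base_rates, "base_rates")
  if (!all(c("early", "late") %in% names(annual_rate_multiplier)) ||
      any(annual_rate_multiplier <= 0)) {
    abort("`annual_rate_multiplier` must be positive values named 'early' and 'late'")
  }
  for (p in c("followup_visit_prob", "sex_ratio", "preterm_prob",
              "comorbidity_prob", "icd9_coded_prob")) {
    stopifnot_scalar_prob(get(p), p)
  }
  for (r in c("recurrence_frailty_sd", "false_positive_text_rate",
              "background_visit_rate", "enrollment_hazard",
              "dropout_hazard")) {
    stopifnot_nonneg(get(r), r)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  structure(
    list(
      n_children = as.integer(n_children),
      study_start = study_start, study_end = study_end,
      base_rates = base_rates[labs],
      annual_rate_multiplier = annual_rate_multiplier[c("early", "late")],
      breakpoint_year = as.integer(breakpoint_year),
      followup_visit_prob = followup_visit_prob,
      recurrence_frailty_sd = recurrence_frailty_sd,
      false_positive_text_rate = false_positive_text_rate,
      background_visit_rate = background_visit_rate,
      enrollment_hazard = enrollment_hazard,
      dropout_hazard = dropout_hazard,
      sex_ratio = sex_ratio,
      preterm_prob = preterm_prob,
      comorbidity_prob = comorbidity_prob,
      icd9_coded_prob = icd9_coded_prob,
      edges = edges,
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

# Calendar-period multiplier for the simulated annual trend.
period_multiplier <- function(year, params) {
  t <- year - year_of(params$study_start)
  tb <- params$breakpoint_year - 1L - year_of(params$study_start)
  early <- params$annual_rate_multiplier[["early"]]
  late <- params$annual_rate_multiplier[["late"]]
  early^pmin(t, tb) * late^pmax(0, t - tb)
}

# Free-text vocabularies. True positives match the otitis patterns; false
# positives match "*om*" in an ordinary word and sit on the bundled
# exclusion list; background strings match nothing.
aom_text_vocab <- function() {
  c("otite media acuta", "otite media purulenta",
    "otite acuta bilaterale", "om purulenta")
}

fp_text_vocab <- function() {
  c("vomito", "vomito e diarrea", "dolore addominale")
}

background_text_vocab <- function() {
  c("", "", "controllo di salute", "febbre", "faringite")
}

aom_icd9_vocab <- function() {
  c("382", "382.0", "382.00", "382.4", "382.9")
}

empty_child_table <- function() {
  tibble(child_id = character(0), birth_date = as.Date(character(0)),
         sex = character(0), registration_date = as.Date(character(0)),
         end_date = as.Date(character(0)), preterm = integer(0),
         comorbidity = integer(0))
}

empty_visit_table <- function() {
  tibble(child_id = character(0), visit_date = as.Date(character(0)),
         icd9 = character(0), free_text = character(0))
}

#' Generate a synthetic child and visit table
#'
#' Simulates the cohort described by [cohort_params()]: demographics and
#' enrollment intervals, AOM episode onsets from the piecewise-constant
#' intensity (age band x calendar year x frailty), index and follow-up
#' visits, false-positive free-text visits, and routine background visits.
#' Identical parameters (including the seed) give identical tables.
#'
#' No visit predates the child's registration or birth, and none postdates
#' the end of follow-up.
#'
#' @param params a [cohort_params()] object.
#' @return a list of class `aom_cohort` with tibbles `children` and
#'   `visits`; the simulated truth is carried internally and retrieved
#'   with [ground_truth()].
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_children = 50, seed = 42))
#' nrow(cohort$children)
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    abort("`params` must be created with cohort_params()")
  }
  set.seed(params$seed)
  n <- params$n_children
  if (n == 0) {
    return(new_cohort(empty_child_table(), empty_visit_table(),
                      truth = tibble(child_id = character(0),
                                     onset_date = as.Date(character(0)),
                                     true_label = character(0)),
                      params = params))
  }
  n_study_days <- as.integer(params$study_end - params$study_start) + 1L
  max_age_days <- floor(params$edges[length(params$edges)] * DAYS_PER_YEAR)

  children <- tibble(
    child_id = sprintf("c%05d", seq_len(n)),
    birth_date = params$study_start +
      floor(runif(n, -(max_age_days - 1), n_study_days)),
    sex = if_else(runif(n) < params$sex_ratio, "M", "F"),
    preterm = rbinom(n, 1, params$preterm_prob),
    comorbidity = rbinom(n, 1, params$comorbidity_prob)
  )
  reg_delay <- if (params$enrollment_hazard > 0) {
    round(rexp(n, rate = params$enrollment_hazard) * DAYS_PER_YEAR)
  } else rep(0, n)
  children$registration_date <- children$birth_date + reg_delay
  followup_len <- if (params$dropout_hazard > 0) {
    round(rexp(n, rate = params$dropout_hazard) * DAYS_PER_YEAR)
  } else rep(Inf, n)
  # administrative records close at study end; children registering after
  # that carry an empty follow-up interval (end = registration)
  children$end_date <- pmax(
    pmin(children$registration_date + followup_len, params$study_end),
    children$registration_date
  )
  children <- select(children, "child_id", "birth_date", "sex",
                     "registration_date", "end_date", "preterm",
                     "comorbidity")

  frailty <- if (params$recurrence_frailty_sd > 0) {
    rlnorm(n, meanlog = -params$recurrence_frailty_sd^2 / 2,
           sdlog = params$recurrence_frailty_sd)
  } else rep(1, n)

  # observation interval per child, clipped to the study window and age range
  obs_start <- pmax(children$registration_date, params$study_start,
                    children$birth_date)
  age_exit <- add_years(children$birth_date,
                        params$edges[length(params$edges)]) - 1
  obs_end <- pmin(children$end_date, params$study_end, age_exit)
  observed <- which(obs_start <= obs_end)

  frags <- purrr::map_dfr(observed, function(i) {
    fr <- split_observation(children$birth_date[i], obs_start[i], obs_end[i],
                            params$edges)
    fr$child_idx <- i
    fr
  })

  truth <- tibble(child_id = character(0),
                  onset_date = as.Date(character(0)))
  if (nrow(frags) > 0) {
    day_rate <- params$base_rates[as.character(frags$age_band)] / 1000 /
      DAYS_PER_YEAR *
      period_multiplier(frags$year, params) *
      frailty[frags$child_idx]
    n_events <- rpois(nrow(frags), frags$days * day_rate)
    idx <- rep(seq_len(nrow(frags)), n_events)
    if (length(idx) > 0) {
      onset <- frags$start[idx] + floor(runif(length(idx), 0, frags$days[idx]))
      truth <- tibble(child_id = children$child_id[frags$child_idx[idx]],
                      onset_date = onset) %>%
        distinct() %>%
        arrange(.data$child_id, .data$onset_date)
    }
  }

  # index visits
  n_ep <- nrow(truth)
  visits <- list()
  if (n_ep > 0) {
    coded <- runif(n_ep) < params$icd9_coded_prob
    visits$index <- tibble(
      child_id = truth$child_id,
      visit_date = truth$onset_date,
      icd9 = if_else(coded,
                     sample(aom_icd9_vocab(), n_ep, replace = TRUE), ""),
      free_text = if_else(coded, "",
                          sample(aom_text_vocab(), n_ep, replace = TRUE))
    )
    # follow-up visits within 14 days of onset
    has_fu <- runif(n_ep) < params$followup_visit_prob
    n_fu <- ifelse(has_fu, 1L + rbinom(n_ep, 1, 0.5), 0L)
    fu_idx <- rep(seq_len(n_ep), n_fu)
    if (length(fu_idx) > 0) {
      offs <- sample(14L, length(fu_idx), replace = TRUE)
      fu_coded <- runif(length(fu_idx)) < params$icd9_coded_prob
      fu <- tibble(
        child_id = truth$child_id[fu_idx],
        visit_date = truth$onset_date[fu_idx] + offs,
        icd9 = if_else(fu_coded,
                       sample(aom_icd9_vocab(), length(fu_idx),
                              replace = TRUE), ""),
        free_text = if_else(fu_coded, "",
                            sample(aom_text_vocab(), length(fu_idx),
                                   replace = TRUE))
      )
      # keep follow-ups inside the child's observation window
      end_by_child <- setNames(obs_end, children$child_id)
      visits$followup <- filter(
        fu, .data$visit_date <= end_by_child[.data$child_id]
      )
    }
  }

  # false-positive and background visits, uniform over the observation days
  extra_visits <- function(rate_per_day, icd9_pool, text_pool) {
    obs_days <- as.numeric(obs_end[observed] - obs_start[observed]) + 1
    k <- rpois(length(observed), obs_days * rate_per_day)
    ridx <- rep(seq_along(observed), k)
    if (length(ridx) == 0) return(NULL)
    i <- observed[ridx]
    tibble(
      child_id = children$child_id[i],
      visit_date = obs_start[i] +
        floor(runif(length(i), 0, as.numeric(obs_end[i] - obs_start[i]) + 1)),
      icd9 = sample(icd9_pool, length(i), replace = TRUE),
      free_text = sample(text_pool, length(i), replace = TRUE)
    )
  }
  if (length(observed) > 0) {
    visits$false_positive <- extra_visits(
      params$false_positive_text_rate / 1000 / DAYS_PER_YEAR,
      "", fp_text_vocab()
    )
    visits$background <- extra_visits(
      params$background_visit_rate / DAYS_PER_YEAR,
      c("", "", "460", "786.2"), background_text_vocab()
    )
  }
  visit_tbl <- bind_rows(visits)
  if (nrow(visit_tbl) == 0) visit_tbl <- empty_visit_table()
  visit_tbl <- arrange(visit_tbl, .data$child_id, .data$visit_date,
                       .data$icd9, .data$free_text)

  truth_labeled <- if (n_ep > 0) {
    classify_episodes(truth) %>%
      rename(true_label = "label") %>%
      select("child_id", "onset_date", "true_label")
  } else {
    tibble(child_id = character(0), onset_date = as.Date(character(0)),
           true_label = character(0))
  }
  new_cohort(children, visit_tbl, truth_labeled, params)
}

new_cohort <- function(children, visits, truth, params) {
  structure(
    list(children = children, visits = visits),
    truth = truth, params = params, class = "aom_cohort"
  )
}

#' @export
print.aom_cohort <- function(x, ...) {
  cat(sprintf("<aom_cohort> %d children, %d visits (seed %d)\n",
              nrow(x$children), nrow(x$visits),
              attr(x, "params")$seed))
  invisible(x)
}

#' Retrieve the simulated ground truth of a cohort
#'
#' Returns the true episode onsets and true simple/recurrent labels (under
#' the default recurrence definition) recorded while the cohort was
#' simulated, enabling recovery tests of the detection pipeline. The
#' configured true stratum rates are attached as the `true_rates`
#' attribute.
#'
#' @param params the [cohort_params()] the cohort was generated with.
#' @param cohort the [simulate_cohort()] result.
#' @return tibble `child_id`, `onset_date`, `true_label`, with a
#'   `true_rates` attribute (tibble `year`, `age_band`, `rate` per 1000
#'   person-years).
#' @export
ground_truth <- function(params, cohort) {
  if (!inherits(cohort, "aom_cohort")) {
    abort("`cohort` must be produced by simulate_cohort()")
  }
  if (!identical(unclass(params), unclass(attr(cohort, "params")))) {
    abort("`params` do not match the parameters this cohort was generated with")
  }
  truth <- attr(cohort, "truth")
  years <- seq(year_of(params$study_start), year_of(params$study_end))
  labs <- age_band_labels(params$edges)
  rates <- tidyr::crossing(year = years, age_band = labs) %>%
    mutate(rate = params$base_rates[.data$age_band] *
             period_multiplier(.data$year, params))
  attr(truth, "true_rates") <- rates
  truth
}
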