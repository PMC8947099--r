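# Person-time accrual: each child's clipped observation interval is split
# at 1 January of each year and at the age-band birthdays, and each fragment
# contributes its (inclusive) day count to exactly one (year, age_band) cell.

# Split one child's observation interval [obs_start, obs_end] (inclusive
# dates) into maximal fragments homogeneous in calendar year and age band.
# Returns a tibble: year, age_band, start, end, days.
split_observation <- function(birth_date, obs_start, obs_end,
                              edges = age_band_edges()) {
  if (is.na(obs_start) || is.na(obs_end) || obs_start > obs_end) {
    return(tibble(year = integer(0),
                  age_band = factor(character(0),
                                    levels = age_band_labels(edges)),
                  start = as.Date(character(0)), end = as.Date(character(0)),
                  days = numeric(0)))
  }
  # candidate fragment starts: Jan 1 of each spanned year, band birthdays
  years <- seq(year_of(obs_start), year_of(obs_end))
  jan1 <- as.Date(sprintf("%d-01-01", years))
  bdays <- add_years(rep(birth_date, length(edges)), edges)
  cuts <- sort(unique(c(jan1, bdays)))
  cuts <- cuts[cuts > obs_start & cuts <= obs_end]
  starts <- c(obs_start, cuts)
  ends <- c(cuts - 1, obs_end)
  tibble(
    year = year_of(starts),
    age_band = age_band_at(rep(birth_date, length(starts)), starts, edges),
    start = starts,
    end = ends,
    days = as.numeric(ends - starts) + 1
  )
}

#' Accrue person-time by calendar year and age band
#'
#' Each child's observation interval runs from the latest of registration,
#' study start and birth, to the earliest of deregistration (death,
#' migration, or end of physician follow-up), study end, and the day before
#' the 15th birthday (the upper age-band edge). The interval is split at
#' 1 January of each year and at the band-edge birthdays; each fragment's
#' inclusive day count goes to exactly one (year, age band) cell.
#' Person-years are days / 365.25.
#'
#' Children with inverted or empty observation intervals contribute zero
#' time, with a warning.
#'
#' @param children child table with `child_id`, `birth_date`,
#'   `registration_date`, `end_date` (and any extra columns, ignored).
#' @param study_start,study_end study window (Date or ISO strings).
#' @param edges age-band edges in years, see [age_band_edges()].
#' @return tibble `child_id`, `year`, `age_band`, `days`, `person_years`.
#' @export
accrue_person_time <- function(children,
                               study_start = as.Date("2010-01-01"),
                               study_end = as.Date("2017-12-31"),
                               edges = age_band_edges()) {
  children <- as_tibble(children)
  study_start <- as_date_strict(study_start, "study_start")
  study_end <- as_date_strict(study_end, "study_end")
  for (col in c("birth_date", "registration_date", "end_date")) {
    children[[col]] <- as_date_strict(children[[col]], col)
  }
  if (nrow(children) == 0) {
    return(tibble(child_id = character(0), year = integer(0),
                  age_band = factor(character(0),
                                    levels = age_band_labels(edges)),
                  days = numeric(0), person_years = numeric(0)))
  }
  obs_start <- pmax(children$registration_date, study_start,
                    children$birth_date)
  age_exit <- add_years(children$birth_date, edges[length(edges)]) - 1
  obs_end <- pmin(children$end_date, study_end, age_exit)
  empty <- is.na(obs_start) | is.na(obs_end) | obs_start > obs_end
  if (any(empty, na.rm = TRUE)) {
    warn(sprintf("%d child(ren) have empty observation intervals and contribute no person-time",
                 sum(empty)))
  }
  frags <- purrr::map(which(!empty), function(i) {
    mutate(
      split_observation(children$birth_date[i], obs_start[i], obs_end[i],
                        edges),
      child_id = children$child_id[i]
    )
  })
  if (length(frags) == 0) {
    return(tibble(child_id = character(0), year = integer(0),
                  age_band = factor(character(0),
                                    levels = age_band_labels(edges)),
                  days = numeric(0), person_years = numeric(0)))
  }
  bind_rows(frags) %>%
    group_by(.data$child_id, .data$year, .data$age_band) %>%
    summarise(days = sum(.data$days), .groups = "drop") %>%
    mutate(person_years = .data$days / DAYS_PER_YEAR)
}

#' Incidence rate per 1000 person-years
#'
#' @param events non-negative event (episode) count.
#' @param person_years positive person-years at risk.
#' @return `1000 * events / person_years`; vectorised.
#' @examples
#' compute_ir(5510, 43692.02)  # 126.1
#' @export
compute_ir <- function(events, person_years) {
  stopifnot_nonneg(events, "events")
  if (any(!is.finite(person_years) | person_years <= 0)) {
    abort("`person_years` must be positive; a rate is undefined on zero person-time")
  }
  1000 * events / person_years
}

#' Poisson normal-approximation confidence interval for an incidence rate
#'
#' The half-width is `z * sqrt(events) / person_years * 1000`; the lower
#' bound is floored at zero. With `z = 1.96` this is the conventional 95%
#' interval for a rate per 1000 person-years.
#'
#' @inheritParams compute_ir
#' @param z normal quantile (default 1.96).
#' @return tibble with columns `ci_low` and `ci_high`; vectorised.
#' @examples
#' compute_ci(5510, 43692.02)  # 122.8 - 129.4
#' @export
compute_ci <- function(events, person_years, z = 1.96) {
  ir <- compute_ir(events, person_years)
  hw <- z * sqrt(events) / person_years * 1000
  tibble(ci_low = pmax(0, ir - hw), ci_high = ir + hw)
}
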