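#' Tabulate incidence rates by stratum
#'
#' Builds annual (or pooled mean annual) incidence tables in the layout of
#' a surveillance report: one row per stratum with the episode count, the
#' person-years at risk, the incidence rate per 1000 person-years, and its
#' 95% confidence interval.
#'
#' Events are attributed to the cell of their onset date. The denominator
#' cells come from [accrue_person_time()]; cells with zero person-years are
#' omitted (never reported as a zero rate), while cells with person-time
#' but no events appear with a rate of 0. When `"label"` is among the
#' strata, simple and recurrent episodes share the same person-time
#' denominator, so their rates add up to the overall rate.
#'
#' @param episodes labeled episode table (from [classify_episodes()] /
#'   [assign_episode_attributes()]) with `calendar_year`, and `age_band`,
#'   `sex`, `label` as needed by `by`.
#' @param person_time output of [accrue_person_time()].
#' @param children child table (needed when `by` includes `"sex"` or a risk
#'   flag, to attach child-level columns to the person-time cells).
#' @param by extra stratification columns: any of `"age_band"`, `"sex"`,
#'   `"label"`, or child-level flag columns such as `"preterm"`.
#' @param pool_years if `TRUE`, pool over calendar years and return the
#'   mean annual rate (total events / total person-years).
#' @param z normal quantile for the CI (default 1.96).
#' @return tibble with the stratum columns, `events`, `person_years`,
#'   `ir`, `ci_low`, `ci_high`.
#' @export
tabulate_incidence <- function(episodes, person_time, children = NULL,
                               by = character(), pool_years = FALSE,
                               z = 1.96) {
  episodes <- as_tibble(episodes)
  person_time <- as_tibble(person_time)
  strata <- c(if (!pool_years) "year", by)
  py_strata <- setdiff(strata, "label")

  child_cols <- setdiff(py_strata, c("year", "age_band"))
  if (length(child_cols) > 0) {
    if (is.null(children)) {
      abort(sprintf("stratifying by %s requires the `children` table",
                    paste(child_cols, collapse = ", ")))
    }
    person_time <- left_join(
      person_time,
      select(as_tibble(children), "child_id", all_of(child_cols)),
      by = "child_id"
    )
  }

  denom <- person_time %>%
    group_by(across(all_of(py_strata))) %>%
    summarise(person_years = sum(.data$person_years), .groups = "drop") %>%
    filter(.data$person_years > 0)
  if ("label" %in% strata) {
    denom <- tidyr::crossing(denom, label = c("simple", "recurrent"))
  }

  ev <- episodes
  if ("year" %in% strata) ev <- rename(ev, year = "calendar_year")
  missing_cols <- setdiff(strata, names(ev))
  if (length(missing_cols) > 0) {
    abort(sprintf("episode table lacks stratum column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  num <- ev %>%
    group_by(across(all_of(strata))) %>%
    summarise(events = dplyr::n(), .groups = "drop")

  joined <- if (length(strata) == 0) {
    mutate(denom, events = sum(num$events, if (nrow(num) == 0) 0L))
  } else {
    denom %>%
      left_join(num, by = strata) %>%
      mutate(events = dplyr::coalesce(.data$events, 0L))
  }
  joined %>%
    mutate(
      ir = compute_ir(.data$events, .data$person_years),
      compute_ci(.data$events, .data$person_years, z = z)
    ) %>%
    select(all_of(strata), "events", "person_years", "ir",
           "ci_low", "ci_high") %>%
    arrange(across(all_of(strata)))
}

#' Round an incidence table for reporting
#'
#' Rates and CI bounds are rounded half-up to integers, the convention of
#' published per-1000-person-year tables; person-years keep two decimals.
#' Internal tables retain full precision -- this is a presentation step.
#'
#' @param incidence output of [tabulate_incidence()].
#' @return the table with rounded `ir`, `ci_low`, `ci_high` and a
#'   formatted `ir_ci` display column.
#' @export
format_incidence <- function(incidence) {
  incidence %>%
    mutate(
      ir = round_half_up(.data$ir),
      ci_low = round_half_up(.data$ci_low),
      ci_high = round_half_up(.data$ci_high),
      person_years = round_half_up(.data$person_years, 2),
      ir_ci = sprintf("%d (%d-%d)", as.integer(.data$ir),
                      as.integer(.data$ci_low), as.integer(.data$ci_high))
    )
}
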