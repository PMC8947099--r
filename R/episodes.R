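#' Episode-grouping and eligibility configuration
#'
#' Controls how AOM visits are grouped into episodes and which children are
#' eligible to contribute episodes.
#'
#' Visits separated by more than `gap_days` belong to different episodes.
#' Under the default `rolling` mode the gap is measured from the previous
#' visit, so a chain of visits each within 14 days of the last forms one
#' episode; under `anchor_to_first` every visit must fall within `gap_days`
#' of the episode's first visit. The two readings differ for chains of three
#' or more visits.
#'
#' Eligibility requires registration at least `pre_index_months` before the
#' first (index) episode -- waived below `pre_index_waiver_age_years` years
#' of age -- and continued registration at least `post_index_months` after
#' it, plus at least `min_distinct_visits` distinct visit dates of any kind.
#' Month windows are converted to fixed day counts (6 months = 183 days,
#' 12 months = 365 days) so the filter is calendar-independent.
#'
#' @param gap_days maximum within-episode gap in days (default 14).
#' @param gap_mode `"rolling"` (consecutive-visit gaps) or
#'   `"anchor_to_first"` (gaps from the episode onset).
#' @param pre_index_months required registration time before the index
#'   episode (default 6).
#' @param post_index_months required registration time after the index
#'   episode (default 12), measured against the child's deregistration
#'   date; children still registered at study end are retained.
#' @param pre_index_waiver_age_years age below which the pre-index
#'   requirement is waived (default 1).
#' @param min_distinct_visits minimum number of distinct visit dates, any
#'   cause (default 2).
#' @return an object of class `episode_config`.
#' @export
episode_config <- function(gap_days = 14L,
                           gap_mode = c("rolling", "anchor_to_first"),
                           pre_index_months = 6L,
                           post_index_months = 12L,
                           pre_index_waiver_age_years = 1,
                           min_distinct_visits = 2L) {
  gap_mode <- match.arg(gap_mode)
  if (!is.numeric(gap_days) || gap_days < 1) abort("`gap_days` must be >= 1")
  stopifnot_nonneg(pre_index_months, "pre_index_months")
  stopifnot_nonneg(post_index_months, "post_index_months")
  stopifnot_nonneg(min_distinct_visits, "min_distinct_visits")
  structure(
    list(
      gap_days = as.integer(gap_days),
      gap_mode = gap_mode,
      pre_index_months = pre_index_months,
      post_index_months = post_index_months,
      pre_index_waiver_age_years = pre_index_waiver_age_years,
      min_distinct_visits = as.integer(min_distinct_visits)
    ),
    class = "episode_config"
  )
}

# Segment one child's sorted unique visit dates into episodes. Returns an
# integer episode index per date.
segment_dates <- function(dates, gap_days, gap_mode) {
  n <- length(dates)
  if (n == 0) return(integer(0))
  idx <- integer(n)
  idx[1] <- 1L
  anchor <- dates[1]
  for (i in seq_len(n)[-1]) {
    ref <- if (gap_mode == "rolling") dates[i - 1L] else anchor
    if (as.numeric(dates[i] - ref) > gap_days) {
      idx[i] <- idx[i - 1L] + 1L
      anchor <- dates[i]
    } else {
      idx[i] <- idx[i - 1L]
    }
  }
  idx
}

#' Group AOM visits into episodes with the gap rule
#'
#' Partitions each child's AOM visits into maximal runs: a gap of more than
#' `gap_days` days between visits (consecutive visits under `rolling` mode;
#' visit-to-onset under `anchor_to_first`) starts a new episode. Same-day
#' duplicate visits are merged into one visit occurrence before grouping.
#' Every visit belongs to exactly one episode.
#'
#' @param aom_visits data frame with columns `child_id` and `visit_date`
#'   (Date or ISO strings), typically from [identify_aom_visits()].
#' @param config an [episode_config()].
#' @return tibble with one row per episode: `child_id`, `episode_seq`,
#'   `onset_date`, `last_visit_date`, `n_visits`.
#' @examples
#' v <- tibble::tibble(
#'   child_id = "c1",
#'   visit_date = as.Date("2012-01-01") + c(0, 10, 20)
#' )
#' build_episodes(v)  # one episode under rolling mode
#' build_episodes(v, episode_config(gap_mode = "anchor_to_first"))  # two
#' @export
build_episodes <- function(aom_visits, config = episode_config()) {
  aom_visits <- as_tibble(aom_visits)
  if (nrow(aom_visits) == 0) {
    return(tibble(
      child_id = character(0), episode_seq = integer(0),
      onset_date = as.Date(character(0)),
      last_visit_date = as.Date(character(0)), n_visits = integer(0)
    ))
  }
  aom_visits$visit_date <- as_date_strict(aom_visits$visit_date, "visit_date")
  aom_visits %>%
    distinct(.data$child_id, .data$visit_date) %>%
    arrange(.data$child_id, .data$visit_date) %>%
    group_by(.data$child_id) %>%
    mutate(episode_seq = segment_dates(.data$visit_date, config$gap_days,
                                       config$gap_mode)) %>%
    group_by(.data$child_id, .data$episode_seq) %>%
    summarise(
      onset_date = min(.data$visit_date),
      last_visit_date = max(.data$visit_date),
      n_visits = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$child_id, .data$onset_date)
}

#' Attach calendar year, exact age, and age band to episodes
#'
#' The calendar year is the year of the episode onset (episodes crossing
#' calendar years belong to the year in which they began). The age band is
#' derived from exact birthday arithmetic: a child is in `2-4` from the
#' second birthday up to (not including) the fifth. Episodes with onset on
#' or after the 15th birthday fall outside the study population and are
#' dropped; the number dropped is recorded in the `n_aged_out` attribute.
#'
#' @param episodes output of [build_episodes()].
#' @param children data frame with `child_id`, `birth_date`, and `sex`.
#' @param edges age-band edges in years, see [age_band_edges()].
#' @return episodes tibble with added `calendar_year`, `age_at_onset`
#'   (years), `age_band`, and `sex` columns.
#' @export
assign_episode_attributes <- function(episodes, children,
                                      edges = age_band_edges()) {
  episodes <- as_tibble(episodes)
  children <- as_tibble(children)
  children$birth_date <- as_date_strict(children$birth_date, "birth_date")
  out <- episodes %>%
    left_join(select(children, "child_id", "birth_date",
                     any_of("sex")), by = "child_id")
  known <- !is.na(out$birth_date)
  if (any(known & out$onset_date < out$birth_date)) {
    abort("episode onset precedes birth date: corrupt input data")
  }
  out <- out %>%
    mutate(
      calendar_year = year_of(.data$onset_date),
      age_at_onset = age_years_at(.data$birth_date, .data$onset_date),
      age_band = age_band_at(.data$birth_date, .data$onset_date, edges)
    )
  aged_out <- known & is.na(out$age_band)
  res <- out[!aged_out, , drop = FALSE] %>% select(-"birth_date")
  attr(res, "n_aged_out") <- sum(aged_out)
  res
}

#' @importFrom dplyr any_of
NULL

#' Apply child-level eligibility filters
#'
#' Drops *all* episodes of a child when the child fails any filter, in this
#' order of precedence: missing birth date (`missing_age`), fewer than
#' `min_distinct_visits` distinct visit dates of any kind (`min_visits`),
#' registration less than the pre-index window before the first episode
#' while at or above the waiver age (`pre_index`), or deregistration less
#' than the post-index window after the first episode (`post_index`).
#'
#' The post-index requirement concerns continued *registration*, so it is
#' waived for children whose follow-up is administratively censored at the
#' study end (`end_date >= study_end`) rather than ended by deregistration:
#' a child whose index episode falls late in the final study year but who
#' is still registered at close-out is retained.
#'
#' @param children child table with `child_id`, `birth_date`,
#'   `registration_date`, `end_date`.
#' @param visits full visit table (all causes), used for the
#'   distinct-visit count.
#' @param episodes episode table with `child_id` and `onset_date`.
#' @param config an [episode_config()].
#' @param study_end study close-out date used for the censoring waiver;
#'   `NULL` applies the post-index requirement to every child.
#' @return list with `episodes` (retained rows, input order) and
#'   `exclusion_log` (tibble `child_id`, `reason`).
#' @export
apply_eligibility <- function(children, visits, episodes,
                              config = episode_config(),
                              study_end = NULL) {
  children <- as_tibble(children)
  episodes <- as_tibble(episodes)
  for (col in c("registration_date", "end_date")) {
    children[[col]] <- as_date_strict(children[[col]], col)
  }
  children$birth_date <- as_date_strict(children$birth_date, "birth_date")
  if (nrow(episodes) == 0) {
    return(list(episodes = episodes,
                exclusion_log = tibble(child_id = character(0),
                                       reason = character(0))))
  }
  visit_counts <- as_tibble(visits) %>%
    distinct(.data$child_id, .data$visit_date) %>%
    count(.data$child_id, name = "n_distinct_visits")

  pre_days <- months_to_days(config$pre_index_months)
  post_days <- months_to_days(config$post_index_months)
  censor_date <- if (is.null(study_end)) {
    # no censoring waiver: a date no end_date can reach
    as.Date(Inf, origin = "1970-01-01")
  } else {
    as_date_strict(study_end, "study_end")
  }

  status <- episodes %>%
    group_by(.data$child_id) %>%
    summarise(index_date = min(.data$onset_date), .groups = "drop") %>%
    left_join(children, by = "child_id") %>%
    left_join(visit_counts, by = "child_id") %>%
    mutate(
      n_distinct_visits = dplyr::coalesce(.data$n_distinct_visits, 0L),
      age_at_index = age_years_at(.data$birth_date, .data$index_date),
      pre_ok = is.na(.data$birth_date) |
        as.numeric(.data$index_date - .data$registration_date) >= pre_days |
        .data$age_at_index < config$pre_index_waiver_age_years,
      post_ok = as.numeric(.data$end_date - .data$index_date) >= post_days |
        .data$end_date >= .env$censor_date,
      reason = dplyr::case_when(
        is.na(.data$birth_date) ~ "missing_age",
        .data$n_distinct_visits < config$min_distinct_visits ~ "min_visits",
        !.data$pre_ok ~ "pre_index",
        !.data$post_ok ~ "post_index",
        TRUE ~ NA_character_
      )
    )
  excluded <- filter(status, !is.na(.data$reason))
  list(
    episodes = filter(episodes, !.data$child_id %in% excluded$child_id),
    exclusion_log = select(excluded, "child_id", "reason")
  )
}
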