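#' Recurrent-AOM classification windows
#'
#' An episode is *recurrent* when the child has accumulated at least
#' `count_short` episodes within the short window (6 months = 183 days) or
#' at least `count_long` within the long window (12 months = 365 days),
#' counting the episode itself, and at least one earlier episode began
#' within the preceding 6 months. All other episodes are *simple*.
#'
#' `label_mode` decides which episodes of a qualifying cluster carry the
#' recurrent label: `"completing"` (default) labels the episode that
#' completes a qualifying window (and any later episode that itself
#' completes one), keeping classification causal; `"cluster"` additionally
#' back-labels every episode inside the qualifying window.
#'
#' @param window_short_days short window length in days (default 183).
#' @param window_long_days long window length in days (default 365).
#' @param count_short episodes required in the short window (default 3).
#' @param count_long episodes required in the long window (default 4).
#' @param preceding_window_days the "preceding 6 months" check (default 183).
#' @param label_mode `"completing"` or `"cluster"`.
#' @return an object of class `recurrence_config`.
#' @export
recurrence_config <- function(window_short_days = 183L,
                              window_long_days = 365L,
                              count_short = 3L,
                              count_long = 4L,
                              preceding_window_days = 183L,
                              label_mode = c("completing", "cluster")) {
  label_mode <- match.arg(label_mode)
  if (window_short_days >= window_long_days) {
    abort("`window_short_days` must be < `window_long_days`")
  }
  if (count_short > count_long) {
    abort("`count_short` must be <= `count_long`")
  }
  for (v in c(window_short_days, window_long_days, count_short, count_long,
              preceding_window_days)) {
    if (!is.numeric(v) || v < 1) abort("recurrence windows and counts must be >= 1")
  }
  structure(
    list(
      window_short_days = as.integer(window_short_days),
      window_long_days = as.integer(window_long_days),
      count_short = as.integer(count_short),
      count_long = as.integer(count_long),
      preceding_window_days = as.integer(preceding_window_days),
      label_mode = label_mode
    ),
    class = "recurrence_config"
  )
}

# Label one child's sorted onset days. Windows are half-open on the left,
# closed at the current onset: (onset - W, onset]. The preceding-episode
# check is strictly before the current onset: [onset - P, onset).
label_onsets <- function(onset_days, config) {
  n <- length(onset_days)
  if (n == 0) return(character(0))
  if (anyDuplicated(onset_days)) {
    abort("duplicate episode onsets within a child; the gap rule guarantees distinct onsets")
  }
  recurrent <- logical(n)
  in_window <- vector("list", n)
  for (i in seq_len(n)) {
    short_lo <- onset_days[i] - config$window_short_days
    long_lo <- onset_days[i] - config$window_long_days
    short_set <- which(onset_days > short_lo & onset_days <= onset_days[i])
    long_set <- which(onset_days > long_lo & onset_days <= onset_days[i])
    preceding <- any(onset_days >= onset_days[i] - config$preceding_window_days &
                       onset_days < onset_days[i])
    qualifies <- (length(short_set) >= config$count_short ||
                    length(long_set) >= config$count_long) && preceding
    recurrent[i] <- qualifies
    if (qualifies) {
      in_window[[i]] <- if (length(short_set) >= config$count_short) {
        short_set
      } else {
        long_set
      }
    }
  }
  if (config$label_mode == "cluster") {
    for (i in which(recurrent)) recurrent[in_window[[i]]] <- TRUE
  }
  if_else(recurrent, "recurrent", "simple")
}

#' Label episodes simple or recurrent
#'
#' Applies the windowed recurrence definition per child. Input is sorted
#' defensively by onset date; a child's first-ever episode is always simple
#' (no preceding episode exists).
#'
#' @param episodes episode table with `child_id` and `onset_date`.
#' @param config a [recurrence_config()].
#' @return the episode tibble with an added `label` column
#'   (`"simple"`/`"recurrent"`), sorted by child and onset.
#' @examples
#' ep <- tibble::tibble(
#'   child_id = "c1",
#'   onset_date = as.Date("2012-01-01") + c(0, 60, 120)
#' )
#' classify_episodes(ep)$label  # third episode is recurrent
#' @export
classify_episodes <- function(episodes, config = recurrence_config()) {
  episodes <- as_tibble(episodes)
  if (nrow(episodes) == 0) {
    episodes$label <- character(0)
    return(episodes)
  }
  episodes$onset_date <- as_date_strict(episodes$onset_date, "onset_date")
  episodes %>%
    arrange(.data$child_id, .data$onset_date) %>%
    group_by(.data$child_id) %>%
    mutate(label = label_onsets(as.numeric(.data$onset_date), config)) %>%
    ungroup()
}

#' Split labeled episodes into simple and recurrent tables
#'
#' @param labeled output of [classify_episodes()].
#' @return list with elements `simple` and `recurrent`; the two tables are
#'   a disjoint partition of the input.
#' @export
split_counts <- function(labeled) {
  labeled <- as_tibble(labeled)
  if (!"label" %in% names(labeled)) {
    abort("`labeled` must carry a `label` column; run classify_episodes() first")
  }
  list(
    simple = filter(labeled, .data$label == "simple"),
    recurrent = filter(labeled, .data$label == "recurrent")
  )
}
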