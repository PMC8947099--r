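# Independent brute-force oracles used by the property and acceptance tests.

# Enumerate all contiguous partitions of a sorted day vector (cut subsets)
# and return the episode assignment of the unique partition that is valid
# under the rolling gap rule: within-episode consecutive gaps <= gap_days,
# between-episode boundary gaps > gap_days. Only feasible for small n.
enumerate_rolling_partition <- function(days, gap_days) {
  n <- length(days)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  stopifnot(n <= 12)
  gaps <- diff(days)
  valid <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- as.logical(bitwAnd(mask, 2^(0:(n - 2))))
    ok <- all(gaps[cuts] > gap_days) && all(gaps[!cuts] <= gap_days)
    if (ok) valid[[length(valid) + 1]] <- cumsum(c(1L, as.integer(cuts)))
  }
  stopifnot(length(valid) == 1)  # maximal-run partition is unique
  valid[[1]]
}

# Validity-and-maximality predicate for a rolling-mode episode table: a
# complete characterisation of the (unique) correct partition, usable at
# any n.
check_rolling_partition <- function(visit_days, episodes, gap_days) {
  visit_days <- sort(unique(visit_days))
  # conservation
  if (sum(episodes$n_visits) != length(visit_days)) return(FALSE)
  # episode intervals ordered and separated by > gap_days
  on <- episodes$onset_day
  la <- episodes$last_day
  if (any(on > la)) return(FALSE)
  if (nrow(episodes) > 1) {
    if (any(on[-1] - la[-nrow(episodes)] <= gap_days)) return(FALSE)
  }
  # within each episode, consecutive visit gaps <= gap_days
  for (i in seq_len(nrow(episodes))) {
    d <- visit_days[visit_days >= on[i] & visit_days <= la[i]]
    if (length(d) != episodes$n_visits[i]) return(FALSE)
    if (length(d) > 1 && any(diff(d) > gap_days)) return(FALSE)
  }
  TRUE
}

# Literal window evaluator for the recurrence definition, written directly
# from the clinical rule: episode i is recurrent iff (>= 3 onsets in the
# 183 days ending at onset_i, or >= 4 in the 365 days ending at onset_i)
# and some onset lies in the 183 days strictly before onset_i.
oracle_recurrent_labels <- function(onset_days,
                                    short_w = 183, long_w = 365,
                                    k_short = 3, k_long = 4, prec_w = 183) {
  onset_days <- sort(onset_days)
  vapply(seq_along(onset_days), function(i) {
    o <- onset_days[i]
    n_short <- 0; n_long <- 0; has_prec <- FALSE
    for (x in onset_days) {
      if (x > o - short_w && x <= o) n_short <- n_short + 1
      if (x > o - long_w && x <= o) n_long <- n_long + 1
      if (x >= o - prec_w && x < o) has_prec <- TRUE
    }
    if ((n_short >= k_short || n_long >= k_long) && has_prec) {
      "recurrent"
    } else {
      "simple"
    }
  }, character(1))
}

# O(n^2) pairwise-sign count for the Mann-Kendall statistic.
oracle_mk_s <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  as.integer(s)
}

# Small helper: visit tibble for one child from day offsets.
visits_on_days <- function(days, child = "c1",
                           origin = as.Date("2012-01-01")) {
  tibble::tibble(child_id = child, visit_date = origin + days)
}

# Child table row constructor with sensible defaults.
make_child <- function(child_id = "c1", birth = "2008-01-01",
                       reg = "2008-01-15", end = "2017-12-31",
                       sex = "M", preterm = 0L, comorbidity = 0L) {
  tibble::tibble(
    child_id = child_id, birth_date = as.Date(birth), sex = sex,
    registration_date = as.Date(reg), end_date = as.Date(end),
    preterm = preterm, comorbidity = comorbidity
  )
}
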