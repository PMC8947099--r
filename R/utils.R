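# Shared date and rounding helpers. All interval arithmetic in the package is
# done at day resolution on base Date objects; person-years are days / 365.25.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.4375  # 365.25 / 12

#' Parse a vector as ISO dates, failing loudly
#'
#' @param x character or Date vector.
#' @param what label used in the error message.
#' @return a `Date` vector; `NA` entries are preserved.
#' @keywords internal
as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf(
      "%d %s value(s) are not parseable ISO dates (first offender: '%s')",
      length(bad), what, as.character(x[bad[1]])
    ))
  }
  out[!is.na(x) & x == ""] <- as.Date(NA)
  out
}

# Add whole years to a date. Feb-29 anniversaries in non-leap years roll
# forward to Mar 1 (POSIXlt normalisation), which keeps birthday boundaries
# deterministic.
add_years <- function(date, n) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + n
  as.Date(lt)
}

# Half-up rounding to `digits` decimals, matching how published rate tables
# round (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Default pediatric age bands
#'
#' Age-band edges in whole years of age: `<2`, `2-4` and `5-14`, with 15
#' years as the exit boundary. Band membership is left-closed: a child enters
#' the `2-4` band on the second birthday.
#'
#' @return an integer vector of band edges `c(0, 2, 5, 15)`.
#' @export
age_band_edges <- function() c(0L, 2L, 5L, 15L)

age_band_labels <- function(edges = age_band_edges()) {
  k <- length(edges) - 1L
  lab <- character(k)
  for (i in seq_len(k)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    lab[i] <- if (lo == 0) sprintf("<%d", hi) else sprintf("%d-%d", lo, hi - 1L)
  }
  lab
}

# Age band of a child on a given date, from exact birthday arithmetic
# (never from fractional ages). Returns NA outside [first edge, last edge).
age_band_at <- function(birth_date, on_date, edges = age_band_edges()) {
  labs <- age_band_labels(edges)
  out <- rep(NA_character_, length(on_date))
  birth_date <- rep_len(birth_date, length(on_date))
  for (i in seq_along(edges[-1])) {
    lo <- add_years(birth_date, edges[i])
    hi <- add_years(birth_date, edges[i + 1L])
    hit <- !is.na(on_date) & on_date >= lo & on_date < hi
    out[hit] <- labs[i]
  }
  factor(out, levels = labs)
}

# Exact age in years on a date (days / 365.25); used for reporting and the
# pre-index waiver threshold.
age_years_at <- function(birth_date, on_date) {
  as.numeric(on_date - birth_date) / DAYS_PER_YEAR
}

months_to_days <- function(months) as.integer(round(months * DAYS_PER_MONTH))

year_of <- function(date) as.integer(format(date, "%Y"))

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative", name))
  }
}
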