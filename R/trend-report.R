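#' Combined trend report: Mann-Kendall + ITS per series
#'
#' Runs the Mann-Kendall test on the annual incidence-rate series and the
#' segmented interrupted time series on the annual counts, for the overall
#' cohort, each age band, and the simple/recurrent episode subsets.
#' Degenerate series (no events, or too few years around the breakpoint)
#' are reported with a note instead of a fit.
#'
#' @param episodes labeled, attributed episode table (columns
#'   `calendar_year`, `age_band`, `label`, ...).
#' @param person_time output of [accrue_person_time()].
#' @param spec an [its_spec()]; covariates in the spec must be resolvable
#'   from the episode/person-time strata (e.g. `age_band`).
#' @param children optional child table, passed through to
#'   [tabulate_incidence()] when covariates need child-level columns.
#' @return an object of class `aom_trend_report`: a list of per-series
#'   results (`annual` incidence tibble, `mk` test, `its` fit or `NULL`,
#'   `note`), with a [tidy()] method giving one combined tibble and an
#'   [autoplot()] method drawing the observed and fitted annual rates.
#' @export
trend_report <- function(episodes, person_time, spec = its_spec(),
                         children = NULL) {
  episodes <- as_tibble(episodes)
  bands <- levels(person_time$age_band)
  series <- list(overall = identity)

  subsets <- c(
    stats::setNames(
      lapply(bands, function(b) function(ep) filter(ep, .data$age_band == b)),
      bands
    ),
    list(
      simple = function(ep) filter(ep, .data$label == "simple"),
      recurrent = function(ep) filter(ep, .data$label == "recurrent")
    )
  )
  series <- c(series, subsets)

  results <- purrr::imap(series, function(f, name) {
    ep <- f(episodes)
    pt <- if (name %in% bands) {
      filter(person_time, .data$age_band == name)
    } else {
      person_time
    }
    # covariates that are constant within the subset cannot be adjusted for
    covs <- spec$covariates
    if (name %in% bands) covs <- setdiff(covs, "age_band")
    sp <- its_spec(breakpoint_year = spec$breakpoint_year,
                   covariates = covs, family = spec$family,
                   alpha = spec$alpha)
    if (nrow(ep) == 0) {
      return(list(series = name, annual = NULL, mk = NULL, its = NULL,
                  note = "no episodes in this subset"))
    }
    annual <- tabulate_incidence(ep, pt, children = children)
    mk <- if (nrow(annual) >= 3) mann_kendall(annual$ir) else NULL
    counts <- tabulate_incidence(ep, pt, children = children,
                                 by = sp$covariates)
    its <- tryCatch(fit_its(counts, sp), error = function(e) e)
    note <- if (inherits(its, "error")) {
      msg <- conditionMessage(its)
      its <- NULL
      msg
    } else NA_character_
    if (inherits(its, "error")) its <- NULL
    list(series = name, annual = annual, mk = mk, its = its, note = note)
  })
  structure(list(results = results, spec = spec),
            class = "aom_trend_report")
}

#' @method tidy aom_trend_report
#' @export
tidy.aom_trend_report <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    if (is.null(r$annual)) {
      return(tibble(series = r$series, term = NA_character_,
                    rate_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p.value = NA_real_,
                    mk_s = NA_integer_, mk_p = NA_real_,
                    dispersion = NA_real_, note = r$note))
    }
    mk_s <- if (!is.null(r$mk)) r$mk$s else NA_integer_
    mk_p <- if (!is.null(r$mk)) r$mk$p_value else NA_real_
    if (is.null(r$its)) {
      return(tibble(series = r$series, term = NA_character_,
                    rate_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p.value = NA_real_,
                    mk_s = mk_s, mk_p = mk_p, dispersion = NA_real_,
                    note = r$note))
    }
    r$its$coefficients %>%
      filter(.data$term %in% c("t", "post", "t_post")) %>%
      mutate(
        series = r$series, mk_s = mk_s, mk_p = mk_p,
        dispersion = r$its$dispersion, note = r$note
      ) %>%
      select("series", "term", "rate_ratio", "ci_low", "ci_high",
             "p.value", "mk_s", "mk_p", "dispersion", "note")
  })
}

#' @export
print.aom_trend_report <- function(x, ...) {
  cat("<aom_trend_report>\n")
  for (r in x$results) {
    cat(sprintf("-- %s --\n", r$series))
    if (!is.null(r$mk)) {
      cat(sprintf("  MK: S = %d, p = %.4g\n", r$mk$s, r$mk$p_value))
    }
    if (!is.null(r$its)) {
      tr <- r$its$period_trends
      cat(sprintf("  ITS: early RR/yr %.3f, late RR/yr %.3f, dispersion %.3g\n",
                  tr$rate_ratio[1], tr$rate_ratio[2], r$its$dispersion))
    }
    if (!is.null(r$note) && !is.na(r$note)) cat("  note:", r$note, "\n")
  }
  invisible(x)
}

#' Plot observed and fitted annual incidence rates
#'
#' Draws the observed annual rates (points) and the segmented ITS fitted
#' rates (lines, one segment per period) for the overall series and each
#' age band, one panel per series.
#'
#' @param object an `aom_trend_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot aom_trend_report
#' @export
autoplot.aom_trend_report <- function(object, ...) {
  keep <- purrr::keep(object$results, ~ !is.null(.x$annual) &&
                        !(.x$series %in% c("simple", "recurrent")))
  obs <- purrr::map_dfr(keep, function(r) {
    mutate(select(r$annual, "year", "ir"), series = r$series)
  })
  fitted <- purrr::map_dfr(keep, function(r) {
    if (is.null(r$its)) return(NULL)
    mutate(its_fitted_rates(r$its), series = r$series)
  })
  order_lv <- unique(obs$series)
  obs$series <- factor(obs$series, levels = order_lv)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$year, y = .data$ir)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(
      x = "Year", y = "Episodes per 1000 person-years",
      title = "Annual AOM incidence with segmented ITS fit"
    ) +
    ggplot2::theme_minimal()
  if (nrow(fitted) > 0) {
    fitted$series <- factor(fitted$series, levels = order_lv)
    p <- p + ggplot2::geom_line(
      data = fitted,
      ggplot2::aes(y = .data$fitted_ir, group = .data$period),
      linewidth = 0.8, colour = "#2166ac"
    ) +
      ggplot2::geom_vline(
        xintercept = object$spec$breakpoint_year - 0.5,
        linetype = "dashed", colour = "grey50"
      )
  }
  p
}
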