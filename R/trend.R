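#' Mann-Kendall test for monotonic trend
#'
#' Computes the Mann-Kendall statistic \eqn{S = \sum_{i<j}
#' \mathrm{sign}(x_j - x_i)} and its tie-corrected variance
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18}
#' (sum over tied groups of size \eqn{t}), then the normal-approximation
#' two-sided p-value from \eqn{Z = S/\sqrt{\mathrm{Var}(S)}} with **no**
#' continuity correction. A constant series yields \eqn{S = 0} and
#' \eqn{p = 1}.
#'
#' @param x ordered numeric series (e.g. annual incidence rates); length
#'   must be at least 3 and all values finite.
#' @return an object of class `mk_test` with fields `s` (statistic),
#'   `var_s`, `z`, `p_value`, and `n`.
#' @examples
#' mann_kendall(c(213, 223, 212, 197, 190, 185, 196, 178))  # p ~ 0.0065
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) abort("Mann-Kendall test requires a series of length >= 3")
  if (any(!is.finite(x))) abort("series values must be finite")
  d <- outer(x, x, "-")
  s <- sum(sign(d[lower.tri(d)]))
  ties <- table(x)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (var_s > 0) s / sqrt(var_s) else 0
  p <- if (var_s > 0) 2 * pnorm(-abs(z)) else 1
  structure(
    list(s = as.integer(s), var_s = var_s, z = z, p_value = p, n = n),
    class = "mk_test"
  )
}

#' @export
print.mk_test <- function(x, ...) {
  cat("Mann-Kendall trend test (normal approximation, no continuity correction)\n")
  cat(sprintf("  n = %d, S = %d, Var(S) = %.3f, Z = %.3f, two-sided p = %.4g\n",
              x$n, x$s, x$var_s, x$z, x$p_value))
  invisible(x)
}

#' @method tidy mk_test
#' @export
tidy.mk_test <- function(x, ...) {
  tibble(statistic = x$s, var_s = x$var_s, z = x$z, p.value = x$p_value)
}

#' @method glance mk_test
#' @export
glance.mk_test <- function(x, ...) {
  tibble(n = x$n, statistic = x$s, p.value = x$p_value)
}

#' Interrupted time series specification
#'
#' Two-period segmented count regression on annual stratified counts with a
#' log person-years offset:
#' \deqn{\log \mu = \beta_0 + \beta_1 t + \beta_2 \, 1[y \ge b] +
#'   \beta_3 (y - b) 1[y \ge b] + \gamma' z}
#' where \eqn{t} is years since the first study year, \eqn{b} the
#' breakpoint year (the first year of the late period), and \eqn{z}
#' stratum covariates. \eqn{e^{\beta_1}} is the early-period annual rate
#' ratio, \eqn{e^{\beta_2}} the immediate level change at the break, and
#' \eqn{e^{\beta_1+\beta_3}} the late-period annual rate ratio.
#'
#' @param breakpoint_year first year of the late period (default 2014).
#' @param covariates character vector of stratum columns to adjust for
#'   (e.g. `c("age_band", "sex")`); entered additively on the log scale.
#' @param family `"negative_binomial"` (dispersion estimated by maximum
#'   likelihood) or `"poisson"`.
#' @param alpha significance level for Wald CIs (default 0.05).
#' @return an object of class `its_spec`.
#' @export
its_spec <- function(breakpoint_year = 2014L,
                     covariates = character(),
                     family = c("negative_binomial", "poisson"),
                     alpha = 0.05) {
  family <- match.arg(family)
  stopifnot_scalar_prob(alpha, "alpha")
  structure(
    list(breakpoint_year = as.integer(breakpoint_year),
         covariates = covariates, family = family, alpha = alpha),
    class = "its_spec"
  )
}

#' Fit a segmented interrupted time series to stratum counts
#'
#' Maximum-likelihood fit of the segmented count model of [its_spec()] to
#' a table of annual (optionally stratified) event counts with person-year
#' offsets. The negative-binomial dispersion is estimated by profiling the
#' shape parameter ([MASS::glm.nb()]); data that are effectively Poisson
#' yield a dispersion near zero and coefficients matching a Poisson fit.
#'
#' @param counts data frame with columns `year`, `events`, `person_years`
#'   (all positive), plus any covariate columns named in the spec.
#' @param spec an [its_spec()].
#' @return an object of class `its_fit` carrying the coefficient table
#'   (log-rate estimates, standard errors, rate ratios with Wald CIs and
#'   p-values), per-period annual trend rate ratios, the dispersion
#'   estimate, a convergence report, and the underlying model object.
#' @export
fit_its <- function(counts, spec = its_spec()) {
  counts <- as_tibble(counts)
  need <- c("year", "events", "person_years", spec$covariates)
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    abort(sprintf("`counts` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(counts$person_years <= 0)) {
    abort("all cells must have positive person_years")
  }
  yrs <- sort(unique(counts$year))
  b <- spec$breakpoint_year
  if (sum(yrs < b) < 2 || sum(yrs >= b) < 2) {
    abort("need at least 2 years on each side of the breakpoint")
  }
  dat <- counts %>%
    mutate(
      t = .data$year - min(yrs),
      post = as.integer(.data$year >= b),
      t_post = (.data$year - b) * .data$post
    )
  rhs <- paste(c("t", "post", "t_post", spec$covariates), collapse = " + ")
  fml <- stats::as.formula(
    paste("events ~", rhs, "+ offset(log(person_years))")
  )
  conv <- list(warnings = character(0))
  capture_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      conv$warnings <<- c(conv$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  nb_boundary <- FALSE
  fit <- if (spec$family == "negative_binomial") {
    # The NB shape MLE diverges (dispersion -> 0) on equidispersed data;
    # the model then degenerates to its Poisson limit, which we fit
    # directly and flag.
    nb <- tryCatch(
      capture_warnings(
        MASS::glm.nb(fml, data = dat,
                     control = stats::glm.control(epsilon = 1e-8,
                                                  maxit = 100))
      ),
      error = function(e) e
    )
    if (inherits(nb, "error") || !is.finite(nb$theta) ||
        nb$theta > 1e7) {
      nb_boundary <- TRUE
      conv$warnings <- c(
        conv$warnings,
        "dispersion estimate at the zero boundary; Poisson limit fitted"
      )
      capture_warnings(glm(fml, data = dat, family = poisson()))
    } else {
      nb
    }
  } else {
    capture_warnings(glm(fml, data = dat, family = poisson()))
  }
  if (!isTRUE(fit$converged)) {
    abort(paste("ITS fit did not converge;",
                paste(conv$warnings, collapse = "; ")))
  }
  est <- coef(fit)
  V <- vcov(fit)
  se <- sqrt(diag(V))
  zq <- qnorm(1 - spec$alpha / 2)
  coef_tbl <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    rate_ratio = exp(unname(est)),
    ci_low = exp(unname(est) - zq * unname(se)),
    ci_high = exp(unname(est) + zq * unname(se)),
    p.value = 2 * pnorm(-abs(unname(est) / unname(se)))
  )
  # per-period annual trend rate ratios; late-period SE via the delta method
  late_est <- est[["t"]] + est[["t_post"]]
  late_se <- sqrt(V["t", "t"] + V["t_post", "t_post"] + 2 * V["t", "t_post"])
  period_tbl <- tibble(
    period = c("early", "late"),
    estimate = c(est[["t"]], late_est),
    std.error = c(se[["t"]], late_se),
    rate_ratio = exp(c(est[["t"]], late_est)),
    ci_low = exp(c(est[["t"]] - zq * se[["t"]], late_est - zq * late_se)),
    ci_high = exp(c(est[["t"]] + zq * se[["t"]], late_est + zq * late_se)),
    p.value = 2 * pnorm(-abs(c(est[["t"]] / se[["t"]], late_est / late_se)))
  )
  dispersion <- if (spec$family == "negative_binomial" && !nb_boundary) {
    1 / fit$theta
  } else {
    0
  }
  structure(
    list(
      coefficients = coef_tbl,
      period_trends = period_tbl,
      dispersion = dispersion,
      spec = spec,
      model = fit,
      data = dat,
      convergence = list(converged = isTRUE(fit$converged),
                         warnings = conv$warnings,
                         iterations = fit$iter)
    ),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  fam <- x$spec$family
  cat(sprintf("Segmented ITS (%s, break at %d)\n", fam,
              x$spec$breakpoint_year))
  main <- filter(x$coefficients,
                 .data$term %in% c("t", "post", "t_post"))
  lab <- c(t = "annual trend (early)", post = "level change",
           t_post = "trend change")
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-20s RR %.3f (%.3f-%.3f), p = %.3g\n",
                lab[[main$term[i]]], main$rate_ratio[i], main$ci_low[i],
                main$ci_high[i], main$p.value[i]))
  }
  late <- filter(x$period_trends, .data$period == "late")
  cat(sprintf("  %-20s RR %.3f (%.3f-%.3f)\n", "annual trend (late)",
              late$rate_ratio, late$ci_low, late$ci_high))
  cat(sprintf("  dispersion = %.4g\n", x$dispersion))
  invisible(x)
}

#' @method tidy its_fit
#' @export
tidy.its_fit <- function(x, ...) x$coefficients

#' @method glance its_fit
#' @export
glance.its_fit <- function(x, ...) {
  tibble(
    dispersion = x$dispersion,
    logLik = as.numeric(stats::logLik(x$model)),
    AIC = stats::AIC(x$model),
    nobs = nrow(x$data),
    converged = x$convergence$converged
  )
}

#' Fitted annual rates from an ITS fit
#'
#' Aggregates fitted cell means to annual rates per 1000 person-years,
#' for plotting against the observed series.
#'
#' @param x an `its_fit`.
#' @return tibble `year`, `fitted_ir`, `period`.
#' @export
its_fitted_rates <- function(x) {
  dat <- x$data
  dat$mu <- as.numeric(predict(x$model, type = "response"))
  dat %>%
    group_by(.data$year) %>%
    summarise(mu = sum(.data$mu), py = sum(.data$person_years),
              .groups = "drop") %>%
    mutate(
      fitted_ir = 1000 * .data$mu / .data$py,
      period = if_else(.data$year >= x$spec$breakpoint_year, "late", "early")
    ) %>%
    select("year", "fitted_ir", "period")
}
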