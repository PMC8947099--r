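test_that("Mann-Kendall S and p behave on canonical series", {
  inc <- mann_kendall(1:8)
  expect_equal(inc$s, 28L)           # n(n-1)/2, perfect concordance
  expect_equal(inc$s, oracle_mk_s(1:8))
  dec <- mann_kendall(8:1)
  expect_equal(dec$s, -28L)
  expect_equal(dec$p_value, inc$p_value)
  flat <- mann_kendall(rep(3, 6))
  expect_equal(flat$s, 0L)
  expect_equal(flat$p_value, 1)
  expect_error(mann_kendall(c(1, 2)), "length")
  expect_error(mann_kendall(c(1, 2, NA)), "finite")
})

test_that("Mann-Kendall matches the brute-force pair count, including ties", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    x <- sample(1:6, n, replace = TRUE)  # many ties
    mk <- mann_kendall(x)
    expect_equal(mk$s, oracle_mk_s(x))
    ties <- table(x)
    v <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    expect_equal(mk$var_s, v)
    if (v > 0) {
      expect_equal(mk$p_value, 2 * pnorm(-abs(mk$s / sqrt(v))))
      expect_equal(sign(mk$z), sign(mk$s))
    }
  }
})

test_that("Mann-Kendall is invariant under strictly increasing transforms", {
  set.seed(8)
  for (rep in 1:30) {
    x <- runif(sample(4:10, 1), 1, 50)
    a <- mann_kendall(x)
    b <- mann_kendall(exp(x / 10))
    c_ <- mann_kendall(2 * x + 3)
    expect_equal(a$s, b$s)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$s, c_$s)
  }
})

its_grid <- function() {
  g <- expand.grid(year = 2010:2017, age_band = c("<2", "2-4", "5-14"),
                   sex = c("M", "F"), stringsAsFactors = FALSE)
  py <- c("<2" = 7000, "2-4" = 12000, "5-14" = 31000)
  g$person_years <- py[g$age_band] / 2
  g
}

test_that("counts exactly proportional to person-time give a null ITS fit", {
  g <- its_grid()
  g$events <- round(g$person_years * 0.1)
  fit <- fit_its(g, its_spec(covariates = c("age_band", "sex")))
  main <- fit$coefficients[fit$coefficients$term %in%
                             c("t", "post", "t_post"), ]
  expect_true(all(abs(main$estimate) < 1e-6))
  expect_true(all(abs(main$rate_ratio - 1) < 1e-5))
  expect_true(all(abs(fit$period_trends$rate_ratio - 1) < 1e-5))
})

test_that("negative-binomial fit reduces to Poisson on equidispersed data", {
  set.seed(21)
  g <- its_grid()
  mu <- g$person_years * 0.1 * 0.95^(g$year - 2010)
  g$events <- rpois(nrow(g), mu)
  nb <- fit_its(g, its_spec(covariates = c("age_band", "sex")))
  po <- fit_its(g, its_spec(covariates = c("age_band", "sex"),
                            family = "poisson"))
  expect_lt(nb$dispersion, 1e-4)
  expect_equal(nb$coefficients$estimate, po$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("the fitted segmented model recovers an injected trend and break", {
  set.seed(22)
  g <- its_grid()
  t <- g$year - 2010
  post <- as.integer(g$year >= 2014)
  mu <- g$person_years * 0.15 * 0.94^t * 0.90^post
  g$events <- rpois(nrow(g), mu)
  fit <- fit_its(g, its_spec(covariates = c("age_band", "sex")))
  early <- fit$period_trends[fit$period_trends$period == "early", ]
  expect_lt(abs(early$estimate - log(0.94)), 3 * early$std.error)
  level <- fit$coefficients[fit$coefficients$term == "post", ]
  expect_lt(abs(level$estimate - log(0.90)), 3 * level$std.error)
  # score equation of the log link: fitted totals match observed totals
  expect_equal(sum(predict(fit$model, type = "response")), sum(g$events),
               tolerance = 1e-6)
})

test_that("overdispersed counts yield a positive dispersion estimate", {
  set.seed(23)
  g <- its_grid()
  mu <- g$person_years * 0.12
  g$events <- rnbinom(nrow(g), mu = mu, size = 5)
  fit <- fit_its(g, its_spec(covariates = c("age_band", "sex")))
  expect_gt(fit$dispersion, 0.05)
  expect_lt(fit$dispersion, 1)
  expect_true(fit$convergence$converged)
})

test_that("ITS input contracts are enforced", {
  g <- its_grid()
  g$events <- 5L
  expect_error(fit_its(g[g$year >= 2013, ]), "breakpoint")
  g2 <- g; g2$person_years[1] <- 0
  expect_error(fit_its(g2), "positive person_years")
  expect_error(fit_its(dplyr::select(g, -events)), "lacks column")
})

test_that("tidiers return one-row-per-term tables", {
  set.seed(24)
  g <- its_grid()
  g$events <- rpois(nrow(g), g$person_years * 0.1)
  fit <- fit_its(g)
  td <- tidy(fit)
  expect_true(all(c("term", "rate_ratio", "ci_low", "ci_high", "p.value")
                  %in% names(td)))
  expect_true(all(td$ci_low <= td$rate_ratio & td$rate_ratio <= td$ci_high))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  mk <- mann_kendall(c(5, 3, 4, 1, 2))
  expect_equal(tidy(mk)$statistic, mk$s)
  expect_equal(glance(mk)$n, 5)
})

test_that("trend_report covers all series and plots", {
  p <- cohort_params(n_children = 400, seed = 31)
  rep <- run_pipeline(run_config(simulate = p))
  tr <- rep$trends
  expect_s3_class(tr, "aom_trend_report")
  expect_setequal(names(tr$results),
                  c("overall", "<2", "2-4", "5-14", "simple", "recurrent"))
  td <- tidy(tr)
  expect_true("overall" %in% td$series)
  plt <- autoplot(tr)
  expect_s3_class(plt, "ggplot")
})

test_that("an empty recurrent subset is reported as a note, not an error", {
  # tiny cohort with rates too low for recurrence
  p <- cohort_params(n_children = 60, base_rates = c("<2" = 10, "2-4" = 10,
                                                     "5-14" = 5),
                     recurrence_frailty_sd = 0, seed = 32)
  rep <- run_pipeline(run_config(simulate = p))
  rec <- rep$trends$results$recurrent
  if (is.null(rec$annual)) {
    expect_match(rec$note, "no episodes")
  } else {
    succeed("recurrent episodes occurred in this draw")
  }
})
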