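test_that("parameter validation names the offending field", {
  expect_error(cohort_params(-1), "n_children")
  expect_error(cohort_params(10, sex_ratio = 1.5), "sex_ratio")
  expect_error(cohort_params(10, followup_visit_prob = -0.1),
               "followup_visit_prob")
  expect_error(cohort_params(10, base_rates = c("<2" = 180, "2-4" = 200)),
               "base_rates")
  expect_error(cohort_params(10, study_start = "2017-01-01",
                             study_end = "2010-01-01"), "study_start")
  expect_error(cohort_params(10, dropout_hazard = -1), "dropout_hazard")
})

test_that("empty and zero-rate cohorts degenerate cleanly", {
  empty <- simulate_cohort(cohort_params(0))
  expect_equal(nrow(empty$children), 0)
  expect_equal(nrow(empty$visits), 0)
  expect_equal(nrow(ground_truth(cohort_params(0), empty)), 0)

  quiet <- cohort_params(
    50, base_rates = c("<2" = 0, "2-4" = 0, "5-14" = 0),
    false_positive_text_rate = 0, seed = 5
  )
  co <- simulate_cohort(quiet)
  def <- case_definition(exclusion_list = default_exclusion_file())
  expect_equal(nrow(identify_aom_visits(co$visits, def)), 0)
  expect_equal(nrow(ground_truth(quiet, co)), 0)
})

test_that("identical parameters and seed give identical tables", {
  p <- cohort_params(150, seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$children, b$children)
  expect_identical(a$visits, b$visits)
  p2 <- cohort_params(150, seed = 100)
  expect_false(identical(simulate_cohort(p2)$visits, a$visits))
})

test_that("visits respect the child's registration, birth, and end dates", {
  p <- cohort_params(300, seed = 12)
  co <- simulate_cohort(p)
  v <- dplyr::left_join(co$visits, co$children, by = "child_id")
  expect_true(all(v$visit_date >= v$birth_date))
  expect_true(all(v$visit_date >= v$registration_date))
  expect_true(all(v$visit_date <= v$end_date))
  # children age out of observation before their 15th birthday
  fifteenth <- as.Date(vapply(as.character(v$birth_date), function(b) {
    as.character(seq(as.Date(b), by = "15 years", length.out = 2)[2])
  }, character(1)))
  expect_true(all(v$visit_date < fifteenth))
})

test_that("ground truth is tied to the generating parameters", {
  p <- cohort_params(40, seed = 3)
  co <- simulate_cohort(p)
  tr <- ground_truth(p, co)
  expect_true(all(c("child_id", "onset_date", "true_label") %in% names(tr)))
  rates <- attr(tr, "true_rates")
  expect_equal(sort(unique(rates$year)), 2010:2017)
  # rate table reflects the configured multiplier structure
  r24 <- rates[rates$age_band == "2-4", ]
  expect_equal(unname(r24$rate[r24$year == 2010]), 200)
  expect_equal(unname(r24$rate[r24$year == 2011] /
                        r24$rate[r24$year == 2010]), 0.94)
  other <- cohort_params(40, seed = 4)
  expect_error(ground_truth(other, co), "do not match")
})

test_that("with no follow-ups or false positives, detection equals truth grouping", {
  p <- cohort_params(250, followup_visit_prob = 0,
                     false_positive_text_rate = 0,
                     background_visit_rate = 0, seed = 17)
  co <- simulate_cohort(p)
  truth <- ground_truth(p, co)
  def <- case_definition(exclusion_list = default_exclusion_file())
  detected <- build_episodes(identify_aom_visits(co$visits, def))
  # every AOM visit is an index visit, so detected episodes are exactly the
  # gap-rule grouping of the true onsets
  expected <- build_episodes(
    tibble::tibble(child_id = truth$child_id, visit_date = truth$onset_date)
  )
  expect_equal(detected, expected)
  # and when all of a child's inter-onset gaps exceed the gap threshold,
  # detected episode count equals the true onset count exactly
  gaps_ok <- truth |>
    dplyr::group_by(child_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(onset_date)) > 14) |
                       dplyr::n() == 1)
  wide <- gaps_ok$child_id[gaps_ok$ok]
  expect_equal(
    nrow(dplyr::filter(detected, child_id %in% wide)),
    nrow(dplyr::filter(truth, child_id %in% wide))
  )
})

test_that("frailty skews episodes toward recurrence-prone children", {
  base <- cohort_params(800, recurrence_frailty_sd = 0, seed = 41)
  frail <- cohort_params(800, recurrence_frailty_sd = 1.2, seed = 41)
  n_rec <- function(p) {
    sum(attr(simulate_cohort(p), "truth")$true_label == "recurrent")
  }
  expect_gt(n_rec(frail), n_rec(base))
})

test_that("false-positive visits match patterns but sit on the exclusion list", {
  p <- cohort_params(200, base_rates = c("<2" = 0, "2-4" = 0, "5-14" = 0),
                     false_positive_text_rate = 300,
                     background_visit_rate = 0, seed = 6)
  co <- simulate_cohort(p)
  fp <- co$visits[co$visits$free_text != "", ]
  expect_gt(nrow(fp), 0)
  no_excl <- case_definition()
  with_excl <- case_definition(exclusion_list = default_exclusion_file())
  expect_true(all(match_freetext(fp$free_text, no_excl)))
  expect_equal(nrow(identify_aom_visits(co$visits, with_excl)), 0)
})
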