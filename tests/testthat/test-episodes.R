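test_that("rolling and anchor gap modes segment the documented examples", {
  v <- visits_on_days(c(0, 10, 20))
  roll <- build_episodes(v)
  expect_equal(nrow(roll), 1)
  expect_equal(roll$onset_date, as.Date("2012-01-01"))
  expect_equal(roll$n_visits, 3L)

  anch <- build_episodes(v, episode_config(gap_mode = "anchor_to_first"))
  expect_equal(nrow(anch), 2)
  expect_equal(anch$n_visits, c(2L, 1L))

  expect_equal(nrow(build_episodes(visits_on_days(c(0, 15)))), 2)
  expect_equal(nrow(build_episodes(visits_on_days(c(0, 14)))), 1)
})

test_that("same-day duplicates merge and empty input yields an empty table", {
  v <- visits_on_days(c(0, 0, 3, 3, 3))
  ep <- build_episodes(v)
  expect_equal(ep$n_visits, 2L)
  expect_equal(nrow(build_episodes(v[0, ])), 0)
})

test_that("rolling segmentation matches the enumeration oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    days <- sort(sample(0:80, n))
    ep <- build_episodes(visits_on_days(days))
    got <- rep(seq_len(nrow(ep)),
               ep$n_visits)[order(order(days))]  # per-visit episode index
    want <- enumerate_rolling_partition(days, 14)
    expect_equal(unname(got), unname(want))
    expect_equal(sum(ep$n_visits), length(days))
  }
})

test_that("increasing gap_days never increases the episode count", {
  set.seed(43)
  for (rep in 1:50) {
    days <- sort(sample(0:200, sample(2:20, 1)))
    counts <- vapply(c(3, 7, 14, 30, 60), function(g) {
      nrow(build_episodes(visits_on_days(days), episode_config(gap_days = g)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("episode attributes: onset year, exact-age bands, ageing out", {
  child <- make_child(birth = "2010-11-15")
  ep <- build_episodes(visits_on_days(c(0, 6), origin = as.Date("2012-12-30")))
  at <- assign_episode_attributes(ep, child)
  expect_equal(at$calendar_year, 2012L)       # follow-up in 2013 is irrelevant
  expect_equal(as.character(at$age_band), "2-4")

  # band boundaries are birthdays, left-closed
  bday2 <- build_episodes(visits_on_days(0, origin = as.Date("2012-11-15")))
  expect_equal(
    as.character(assign_episode_attributes(bday2, child)$age_band), "2-4"
  )
  before2 <- build_episodes(visits_on_days(0, origin = as.Date("2012-11-14")))
  expect_equal(
    as.character(assign_episode_attributes(before2, child)$age_band), "<2"
  )

  old <- make_child(birth = "2000-06-01")
  eve15 <- build_episodes(visits_on_days(0, origin = as.Date("2015-05-31")))
  expect_equal(
    as.character(assign_episode_attributes(eve15, old)$age_band), "5-14"
  )
  on15 <- build_episodes(visits_on_days(0, origin = as.Date("2015-06-01")))
  res <- assign_episode_attributes(on15, old)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "n_aged_out"), 1L)
})

test_that("onset before birth is a hard error", {
  ep <- build_episodes(visits_on_days(0, origin = as.Date("2005-01-01")))
  expect_error(assign_episode_attributes(ep, make_child(birth = "2008-01-01")),
               "precedes birth")
})

test_that("eligibility drops and retains children per the window rules", {
  cfg <- episode_config()
  # registered 4 months before index, age 3 at index -> dropped, pre_index
  ch <- make_child(birth = "2010-03-01", reg = "2013-02-01")
  vis <- visits_on_days(c(0, 30), origin = as.Date("2013-06-01"))
  ep <- build_episodes(vis)
  out <- apply_eligibility(ch, vis, ep, cfg)
  expect_equal(nrow(out$episodes), 0)
  expect_equal(out$exclusion_log$reason, "pre_index")

  # same interval but age 0.5 at index -> waived, retained
  ch2 <- make_child(birth = "2012-12-01", reg = "2013-02-01")
  out2 <- apply_eligibility(ch2, vis, ep, cfg)
  expect_equal(nrow(out2$episodes), nrow(ep))
  expect_equal(nrow(out2$exclusion_log), 0)

  # a single distinct visit date -> min_visits
  ch3 <- make_child(reg = "2008-01-15")
  vis3 <- visits_on_days(0, origin = as.Date("2012-06-01"))
  out3 <- apply_eligibility(ch3, vis3, build_episodes(vis3), cfg)
  expect_equal(out3$exclusion_log$reason, "min_visits")

  # deregistration 4 months after index -> post_index ...
  ch4 <- make_child(reg = "2008-01-15", end = "2013-10-01")
  vis4 <- visits_on_days(c(0, 20), origin = as.Date("2013-06-01"))
  out4 <- apply_eligibility(ch4, vis4, build_episodes(vis4), cfg)
  expect_equal(out4$exclusion_log$reason, "post_index")
  # ... unless follow-up is administratively censored at study end
  ch5 <- make_child(reg = "2008-01-15", end = "2017-12-31")
  vis5 <- visits_on_days(c(0, 20), origin = as.Date("2017-06-01"))
  out5 <- apply_eligibility(ch5, vis5, build_episodes(vis5), cfg,
                            study_end = "2017-12-31")
  expect_equal(nrow(out5$exclusion_log), 0)

  # missing birth date -> missing_age
  ch6 <- make_child(); ch6$birth_date <- as.Date(NA)
  out6 <- apply_eligibility(ch6, vis, ep, cfg)
  expect_equal(out6$exclusion_log$reason, "missing_age")
})

test_that("visit conservation holds for retained children", {
  set.seed(77)
  vis <- dplyr::bind_rows(lapply(1:30, function(i) {
    visits_on_days(sort(sample(0:900, sample(2:12, 1))),
                   child = sprintf("k%02d", i))
  }))
  ep <- build_episodes(vis)
  per_child_ep <- dplyr::count(ep, child_id, wt = n_visits)
  per_child_vis <- dplyr::count(dplyr::distinct(vis, child_id, visit_date),
                                child_id)
  expect_equal(per_child_ep$n, per_child_vis$n)
})
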