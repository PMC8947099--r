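def <- case_definition(exclusion_list = default_exclusion_file())

test_that("ICD-9 prefix matching anchors at a code-field boundary", {
  expect_true(all(match_icd9(c("382", "382.0", "382.00", "382.9",
                               " 382.4 "), def)))
  expect_false(any(match_icd9(c("381.00", "38", "3821", "038.2", "1382"),
                              def)))
  expect_false(any(match_icd9(c("", NA), def)))
})

test_that("free-text matching is token-anchored and exclusion-aware", {
  expect_true(match_freetext("otite media acuta", def))
  expect_true(match_freetext("OTITE MEDIA", def))     # case-insensitive
  expect_true(match_freetext("sospetta om purulenta", def))  # om* token
  expect_true(match_freetext("sindrome influenzale", def))   # *om* inside token
  expect_false(match_freetext("", def))
  expect_false(match_freetext(NA, def))
  # pattern hits but the full string is on the exclusion list
  expect_false(match_freetext("vomito", def))
  expect_false(match_freetext("VOMITO", def))
  # same token, different full string, not excluded -> matches
  expect_true(match_freetext("vomito persistente", def))
})

test_that("prefix patterns require the token start, substring do not", {
  pref_only <- case_definition(
    text_patterns = tibble::tibble(pattern = "om", mode = "prefix")
  )
  expect_false(match_freetext("vomito", pref_only))
  expect_true(match_freetext("om destro", pref_only))
  sub_only <- case_definition(
    text_patterns = tibble::tibble(pattern = "om", mode = "substring")
  )
  expect_true(match_freetext("vomito", sub_only))
})

test_that("identify_aom_visits keeps the hand-counted subset with rule flags", {
  v <- tibble::tibble(
    child_id = sprintf("c%02d", 1:10),
    visit_date = as.Date("2013-05-01") + 0:9,
    icd9 = c("382.9", "382.0", "382", "", "", "", "460", "", "", ""),
    free_text = c("", "", "", "otite", "otite media", "vomito",
                  "", "febbre", "tosse", "controllo")
  )
  out <- identify_aom_visits(v, def)
  expect_equal(nrow(out), 5)
  expect_equal(out$match_rule, c("icd9", "icd9", "icd9", "text", "text"))
  expect_equal(out$child_id, sprintf("c%02d", 1:5))  # order preserved
  expect_equal(attr(out, "n_rejected"), 0L)
})

test_that("secondary-position codes in a delimited field are checked", {
  v <- tibble::tibble(child_id = "c1", visit_date = as.Date("2013-05-01"),
                      icd9 = "460; 382.9", free_text = "")
  expect_equal(identify_aom_visits(v, def)$match_rule, "icd9")
})

test_that("empty input and malformed dates are handled", {
  empty <- tibble::tibble(child_id = character(0),
                          visit_date = as.Date(character(0)),
                          icd9 = character(0), free_text = character(0))
  expect_equal(nrow(identify_aom_visits(empty, def)), 0)
  v <- tibble::tibble(child_id = c("a", "b"),
                      visit_date = c("2013-05-01", "not-a-date"),
                      icd9 = c("382.9", "382.9"), free_text = "")
  expect_warning(out <- identify_aom_visits(v, def), "unparseable")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_rejected"), 1L)
})

test_that("identification is idempotent and equals the union of the two rules", {
  set.seed(401)
  v <- tibble::tibble(
    child_id = sprintf("c%03d", 1:200),
    visit_date = as.Date("2012-01-01") + sample(0:2000, 200, TRUE),
    icd9 = sample(c("", "382.9", "382.00", "460", "381.0"), 200, TRUE),
    free_text = sample(c("", "otite media acuta", "vomito", "febbre",
                         "om purulenta", "tosse"), 200, TRUE)
  )
  once <- identify_aom_visits(v, def)
  twice <- identify_aom_visits(once, def)
  expect_equal(as.data.frame(twice), as.data.frame(once))

  icd_only <- case_definition(
    text_patterns = tibble::tibble(pattern = "zzzz", mode = "prefix"),
    exclusion_list = read_exclusion_list(default_exclusion_file())
  )
  txt_only <- case_definition(
    icd9_prefixes = "zzzz",
    exclusion_list = read_exclusion_list(default_exclusion_file())
  )
  a <- identify_aom_visits(v, icd_only)
  b <- identify_aom_visits(v, txt_only)
  union_keys <- sort(unique(c(
    paste(a$child_id, a$visit_date), paste(b$child_id, b$visit_date)
  )))
  both <- identify_aom_visits(v, def)
  expect_equal(sort(paste(both$child_id, both$visit_date)), union_keys)
})

test_that("enlarging the exclusion list never increases the match count", {
  v <- tibble::tibble(
    child_id = sprintf("c%03d", 1:50),
    visit_date = as.Date("2012-01-01") + 1:50,
    icd9 = "",
    free_text = rep(c("otite media acuta", "vomito persistente",
                      "om purulenta", "vomito", "febbre"), 10)
  )
  excl <- read_exclusion_list(default_exclusion_file())
  n_prev <- Inf
  for (extra in list(character(0), "vomito persistente",
                     c("vomito persistente", "om purulenta"))) {
    d <- case_definition(exclusion_list = c(excl, extra))
    n_now <- nrow(identify_aom_visits(v, d))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})
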