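#' Validate raw child and visit tables
#'
#' Schema, date-parsability, referential-integrity, and chronology checks
#' on the two input tables. Returns one row per check with a pass flag,
#' the number of offending rows, and a small sample of offenders.
#'
#' @param children child table (`child_id`, `birth_date`, `sex`,
#'   `registration_date`, `end_date`, ...).
#' @param visits visit table (`child_id`, `visit_date`, `icd9`,
#'   `free_text`).
#' @return tibble `check`, `pass`, `n_fail`, `examples`.
#' @export
validate_inputs <- function(children, visits) {
  children <- as_tibble(children)
  visits <- as_tibble(visits)
  checks <- list()
  add <- function(name, fail_idx, examples = character(0)) {
    checks[[length(checks) + 1]] <<- tibble(
      check = name, pass = length(fail_idx) == 0,
      n_fail = length(fail_idx),
      examples = paste(utils::head(examples, 3), collapse = ", ")
    )
  }

  need_child <- c("child_id", "birth_date", "registration_date", "end_date")
  miss <- setdiff(need_child, names(children))
  add("child_schema", miss, miss)
  need_visit <- c("child_id", "visit_date")
  miss_v <- setdiff(need_visit, names(visits))
  add("visit_schema", miss_v, miss_v)
  if (length(miss) > 0 || length(miss_v) > 0) {
    return(bind_rows(checks))
  }

  parse_ok <- function(x) {
    x <- as.character(x)
    is.na(x) | x == "" |
      !is.na(as.Date(x, format = "%Y-%m-%d", optional = TRUE))
  }
  bad_dates <- which(!parse_ok(visits$visit_date))
  add("visit_dates_iso", bad_dates,
      as.character(visits$visit_date[bad_dates]))
  bad_cdates <- which(!(parse_ok(children$birth_date) &
                          parse_ok(children$registration_date) &
                          parse_ok(children$end_date)))
  add("child_dates_iso", bad_cdates, children$child_id[bad_cdates])

  dup <- which(duplicated(children$child_id))
  add("unique_child_ids", dup, children$child_id[dup])

  orphan <- which(!visits$child_id %in% children$child_id)
  add("referential_integrity", orphan, unique(visits$child_id[orphan]))

  if (length(bad_dates) == 0 && length(bad_cdates) == 0) {
    birth <- setNames(as_date_strict(children$birth_date, "birth_date"),
                      children$child_id)
    vd <- as_date_strict(visits$visit_date, "visit_date")
    known <- visits$child_id %in% children$child_id
    pre_birth <- which(known & !is.na(birth[visits$child_id]) &
                         vd < birth[visits$child_id])
    add("visit_after_birth", pre_birth, unique(visits$child_id[pre_birth]))

    reg <- as_date_strict(children$registration_date, "registration_date")
    endd <- as_date_strict(children$end_date, "end_date")
    inverted <- which(!is.na(reg) & !is.na(endd) & endd < reg)
    add("registration_before_end", inverted, children$child_id[inverted])
  }
  bind_rows(checks)
}

#' Assemble a pipeline run configuration
#'
#' A run configuration holds either file paths to a child and visit table
#' (`input`) or simulation parameters (`simulate`) -- exactly one of the
#' two -- plus the analysis settings for every stage. `run_config()`
#' accepts the same structure as a YAML file read by
#' [read_run_config()].
#'
#' @param input `list(children = path, visits = path)` of CSV paths, or
#'   `NULL` when simulating.
#' @param simulate a [cohort_params()] object (or a list of its
#'   arguments), or `NULL` when reading files.
#' @param exclusion_list path to the free-text exclusion file; defaults to
#'   the bundled fixture.
#' @param case a [case_definition()]; built from `exclusion_list` when
#'   omitted.
#' @param episode an [episode_config()].
#' @param recurrence a [recurrence_config()].
#' @param its an [its_spec()].
#' @param study_start,study_end study window.
#' @param edges age-band edges.
#' @param output_dir directory for the interface files, or `NULL` to skip
#'   writing.
#' @param seed integer seed applied to any simulation.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       exclusion_list = default_exclusion_file(),
                       case = NULL,
                       episode = episode_config(),
                       recurrence = recurrence_config(),
                       its = its_spec(),
                       study_start = "2010-01-01",
                       study_end = "2017-12-31",
                       edges = age_band_edges(),
                       output_dir = NULL,
                       seed = 1L) {
  if (is.null(input) == is.null(simulate)) {
    abort("exactly one of `input` and `simulate` must be given")
  }
  if (!is.null(simulate) && !inherits(simulate, "cohort_params")) {
    simulate$seed <- simulate$seed %||% seed
    simulate <- do.call(cohort_params, simulate)
  }
  if (is.null(case)) {
    case <- case_definition(exclusion_list = read_exclusion_list(exclusion_list))
  }
  structure(
    list(input = input, simulate = simulate, case = case,
         episode = episode, recurrence = recurrence, its = its,
         study_start = as_date_strict(study_start, "study_start"),
         study_end = as_date_strict(study_end, "study_end"),
         edges = edges, output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file whose top-level keys mirror the `run_config()`
#'   arguments; nested blocks (`simulate`, `episode`, `recurrence`,
#'   `its`) are passed to the corresponding constructors.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$simulate)) args$simulate <- y$simulate
  for (k in c("exclusion_list", "study_start", "study_end", "output_dir",
              "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$episode)) args$episode <- do.call(episode_config, y$episode)
  if (!is.null(y$recurrence)) {
    args$recurrence <- do.call(recurrence_config, y$recurrence)
  }
  if (!is.null(y$its)) args$its <- do.call(its_spec, y$its)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the bundled free-text exclusion fixture
#' @return file path of the installed exclusion list.
#' @export
default_exclusion_file <- function() {
  system.file("extdata", "freetext_exclusions.txt", package = "aomcohort",
              mustWork = TRUE)
}

#' Run the full AOM burden pipeline
#'
#' Executes the stage chain: (optionally) simulate the cohort, validate
#' inputs, identify AOM-related visits, build episodes with the gap rule,
#' apply child-level eligibility, classify episodes as simple/recurrent,
#' accrue person-time, tabulate annual and mean annual incidence, and run
#' the trend analyses. Identical configuration and seed give identical
#' outputs. When `output_dir` is set, the interface files (episodes,
#' exclusion log, incidence tables, trend results, a run report, and the
#' ITS figure) are written there.
#'
#' @param config a [run_config()] or a path to a YAML config file.
#' @return an object of class `aom_run_report`: stage-by-stage row counts,
#'   the retained tables, the incidence tables, and the
#'   [trend_report()] object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config or a YAML path")
  }
  stages <- list()
  note_stage <- function(name, rows_in, rows_out) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = name, rows_in = rows_in, rows_out = rows_out,
      rows_excluded = rows_in - rows_out
    )
  }

  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    children <- cohort$children
    visits <- cohort$visits
  } else {
    children <- readr::read_csv(config$input$children,
                                show_col_types = FALSE)
    visits <- readr::read_csv(config$input$visits, show_col_types = FALSE)
    visits$icd9 <- as.character(visits$icd9 %||% "")
    visits$free_text <- as.character(visits$free_text %||% "")
  }
  validation <- validate_inputs(children, visits)
  if (!all(validation$pass)) {
    bad <- validation$check[!validation$pass]
    abort(sprintf("input validation failed at stage 'validate': %s",
                  paste(bad, collapse = ", ")))
  }

  aom <- identify_aom_visits(visits, config$case)
  note_stage("identify", nrow(visits), nrow(aom))

  episodes <- build_episodes(aom, config$episode)
  note_stage("build_episodes", nrow(aom), nrow(episodes))

  episodes <- assign_episode_attributes(episodes, children, config$edges)
  elig <- apply_eligibility(children, visits, episodes, config$episode,
                            study_end = config$study_end)
  note_stage("eligibility", nrow(episodes) + attr(episodes, "n_aged_out"),
             nrow(elig$episodes))

  labeled <- classify_episodes(elig$episodes, config$recurrence)
  note_stage("classify", nrow(elig$episodes), nrow(labeled))

  person_time <- suppressWarnings(
    accrue_person_time(children, config$study_start, config$study_end,
                       config$edges)
  )
  in_study <- filter(labeled,
                     .data$calendar_year >= year_of(config$study_start),
                     .data$calendar_year <= year_of(config$study_end))
  note_stage("study_window", nrow(labeled), nrow(in_study))

  incidence <- list(
    annual = tabulate_incidence(in_study, person_time),
    by_age = tabulate_incidence(in_study, person_time, by = "age_band"),
    by_sex = tabulate_incidence(in_study, person_time, children,
                                by = "sex", pool_years = TRUE),
    by_label = tabulate_incidence(in_study, person_time, by = "label"),
    mean_annual = tabulate_incidence(in_study, person_time,
                                     pool_years = TRUE),
    mean_by_age = tabulate_incidence(in_study, person_time,
                                     by = "age_band", pool_years = TRUE)
  )
  trends <- trend_report(in_study, person_time, config$its, children)

  report <- structure(
    list(
      stages = bind_rows(stages),
      validation = validation,
      n_children = nrow(children),
      total_person_years = sum(person_time$person_years),
      exclusion_log = elig$exclusion_log,
      exclusion_tally = count(elig$exclusion_log, .data$reason),
      episodes = labeled,
      person_time = person_time,
      incidence = incidence,
      trends = trends,
      seed = config$seed,
      config = config
    ),
    class = "aom_run_report"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(report, config$output_dir)
  }
  report
}

#' @export
print.aom_run_report <- function(x, ...) {
  cat("<aom_run_report>\n")
  cat(sprintf("  children: %d, person-years: %.1f\n", x$n_children,
              x$total_person_years))
  print(x$stages)
  invisible(x)
}

write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, name))
  }
  w(report$episodes, "episodes.csv")
  w(report$exclusion_log, "exclusion_log.csv")
  w(report$incidence$annual, "incidence_annual.csv")
  w(report$incidence$by_age, "incidence_by_age_band.csv")
  w(report$incidence$by_sex, "incidence_by_sex.csv")
  w(report$incidence$by_label, "incidence_by_label.csv")
  w(report$incidence$mean_annual, "incidence_mean_annual.csv")
  w(tidy(report$trends), "trend_results.csv")
  w(report$stages, "stage_counts.csv")
  yaml::write_yaml(
    list(seed = report$seed, n_children = report$n_children,
         total_person_years = report$total_person_years,
         exclusions = setNames(as.list(report$exclusion_tally$n),
                               report$exclusion_tally$reason),
         r_version = as.character(getRversion()),
         package_version = as.character(
           utils::packageVersion("aomcohort"))),
    file.path(dir, "run_report.yaml")
  )
  fig <- tryCatch(
    {
      p <- autoplot(report$trends)
      ggplot2::ggsave(file.path(dir, "its_fit.pdf"), p,
                      width = 9, height = 6)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!fig) warn("could not render the ITS figure; tabular outputs written")
  invisible(report)
}
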