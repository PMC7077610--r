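#' Validate a bundle of study tables
#'
#' Runs schema, range and referential checks over the standard table bundle
#' and returns a report of violations (empty when clean) rather than
#' erroring: affect subscales must lie in \[1, 9\] (items likewise), effort
#' items in \[0, 10\], kills/deaths nonnegative, session indexes within the
#' design, and every participant appearing in a child table must exist in
#' `persons`.
#'
#' @param tables Named list of data frames; recognized names are `persons`,
#'   `affect`, `trials`, `effort_items`, `outcomes` (any subset).
#' @param n_sessions Design length for session-range checks.
#' @return A tibble with columns `table`, `row`, `column`, `problem`;
#'   zero rows when every check passes.
#' @export
validate_inputs <- function(tables, n_sessions = 14) {
  out <- list()
  add <- function(table, rows, column, problem) {
    if (length(rows) > 0) {
      out[[length(out) + 1]] <<- tibble(
        table = table, row = as.integer(rows), column = column,
        problem = problem
      )
    }
  }
  range_check <- function(tbl, name, cols, lo, hi) {
    for (col in intersect(cols, names(tbl))) {
      bad <- which(!is.na(tbl[[col]]) & (tbl[[col]] < lo | tbl[[col]] > hi))
      add(name, bad, col, sprintf("outside [%g, %g]", lo, hi))
    }
  }
  if (!is.null(tables$affect)) {
    range_check(tables$affect, "affect",
                c("pa", "pd", "na", "nd", unlist(panas_items())), 1, 9)
    if ("session_index" %in% names(tables$affect)) {
      bad <- which(!tables$affect$session_index %in% seq_len(n_sessions))
      add("affect", bad, "session_index", "outside design range")
    }
  }
  if (!is.null(tables$effort_items)) {
    range_check(tables$effort_items, "effort_items",
                paste0("effort_", 1:6), 0, 10)
  }
  if (!is.null(tables$trials)) {
    for (col in intersect(c("kills", "deaths"), names(tables$trials))) {
      bad <- which(tables$trials[[col]] < 0)
      add("trials", bad, col, "negative count")
    }
  }
  if (!is.null(tables$persons)) {
    known <- tables$persons$participant_id
    for (name in setdiff(names(tables), "persons")) {
      tbl <- tables[[name]]
      if (!is.null(tbl) && "participant_id" %in% names(tbl)) {
        bad <- which(!tbl$participant_id %in% known)
        add(name, bad, "participant_id", "not present in persons table")
      }
    }
  }
  if (length(out) == 0) {
    tibble(table = character(), row = integer(), column = character(),
           problem = character())
  } else {
    bind_rows(out)
  }
}

write_stage <- function(tbl, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  readr::write_csv(tbl, path)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> score -> metrics ->
#' design -> fit -> report, writing every stage's table as CSV under
#' `out_dir` together with a machine-readable `manifest.json` (package
#' version, seed, config hash, row counts, exclusion summary,
#' log-likelihood ladder). Exactly one of `simulation` and `inputs` must be
#' supplied.
#'
#' @param out_dir Output directory (created if needed).
#' @param simulation A [sim_config()] to generate the study, or `NULL`.
#' @param inputs Named list of CSV paths (`persons`, `affect`, `trials`,
#'   `effort_items`) for an observed-data run, or `NULL`.
#' @param n_sessions,change_after Design parameters.
#' @param spin_variant,sd_type Metric options, passed to
#'   [affect_profiles()].
#' @param flatline_threshold Passed to [exclusion_screen()].
#' @param fit_ladders Fit the effort/performance model ladders (set `FALSE`
#'   for a scoring-only run).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         simulation = NULL, inputs = NULL,
                         n_sessions = 14, change_after = 7,
                         spin_variant = "circular_sd", sd_type = "sample",
                         flatline_threshold = 2,
                         fit_ladders = TRUE) {
  if (is.null(simulation) == is.null(inputs)) {
    abort("Supply exactly one of `simulation` and `inputs`.",
          class = "spinpulse_error_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(simulation)) {
    study <- simulate_study(simulation)
    tables <- study[c("persons", "affect", "trials", "effort_items")]
    n_sessions <- simulation$n_sessions
    change_after <- simulation$change_after
    seed <- simulation$seed
  } else {
    tables <- purrr::map(inputs, readr::read_csv, show_col_types = FALSE)
    seed <- NA
  }

  report <- validate_inputs(tables, n_sessions = n_sessions)
  write_stage(report, out_dir, "validation_report")

  scored_trials <- trial_scores(tables$trials)
  sessions <- collapse_sessions(scored_trials)
  effort_sessions <- score_effort(tables$effort_items) |>
    select("participant_id", "session_index", "effort")
  sessions <- left_join(sessions, effort_sessions,
                        by = c("participant_id", "session_index"))
  screen <- exclusion_screen(sessions, n_sessions_expected = n_sessions,
                             flatline_threshold = flatline_threshold)
  write_stage(screen, out_dir, "exclusion_report")
  kept <- screen$participant_id[screen$keep]
  sessions <- filter(sessions, .data$participant_id %in% kept)

  profiles <- affect_profiles(
    filter(tables$affect, .data$participant_id %in% kept),
    spin_variant = spin_variant, sd_type = sd_type
  )
  write_stage(profiles, out_dir, "affect_profiles")

  person_cols <- intersect(
    c("participant_id", "gender", "ability", "vge", "openness",
      "conscientiousness", "extraversion", "agreeableness",
      "emotional_stability"),
    names(tables$persons)
  )
  long <- sessions |>
    left_join(tables$persons[person_cols], by = "participant_id") |>
    left_join(profiles, by = "participant_id") |>
    attach_design(n_sessions = n_sessions, change_after = change_after)
  write_stage(long, out_dir, "analysis_long")

  manifest <- list(
    package = "spinpulse",
    version = as.character(utils::packageVersion("spinpulse")),
    seed = seed,
    config_hash = rlang::hash(list(n_sessions, change_after, spin_variant,
                                   sd_type, flatline_threshold)),
    n_participants = length(kept),
    n_excluded = sum(!screen$keep),
    exclusion_reasons = as.list(table(screen$reason[!screen$keep])),
    rows = list(sessions = nrow(sessions), long = nrow(long),
                trials = nrow(tables$trials)),
    n_validation_issues = nrow(report)
  )

  if (fit_ladders) {
    eff <- model_sequence(long, "effort")
    perf <- model_sequence(long, "performance")
    for (m in names(eff$fits)) {
      write_stage(tidy(eff$fits[[m]]), out_dir, paste0("effort_", m))
    }
    for (m in names(perf$fits)) {
      write_stage(tidy(perf$fits[[m]]), out_dir, paste0("performance_", m))
    }
    write_stage(bind_rows(
      mutate(eff$comparison, outcome = "effort"),
      mutate(perf$comparison, outcome = "performance")
    ), out_dir, "loglik_comparison")
    write_stage(hypothesis_report(eff, perf), out_dir, "hypothesis_report")
    slopes <- bind_rows(
      mutate(simple_slopes(eff$fits$model5, "spin"), moderator_name = "spin"),
      mutate(simple_slopes(eff$fits$model5, "pulse"), moderator_name = "pulse")
    )
    write_stage(slopes, out_dir, "effort_simple_slopes")
    manifest$loglik <- list(
      effort = setNames(eff$comparison$logLik, eff$comparison$model),
      performance = setNames(perf$comparison$logLik, perf$comparison$model)
    )
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
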