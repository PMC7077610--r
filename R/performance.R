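#' Normalized rank term from finishing place
#'
#' Converts a finishing place (1 = first) among `n_competitors` players into
#' a standing in \[0, 1\], with 1 for first place and 0 for last:
#' `(n_competitors - place) / (n_competitors - 1)`.
#'
#' @param place Integer vector of finishing places, 1-based.
#' @param n_competitors Number of players in the trial (participant + bots).
#' @return Numeric vector in \[0, 1\].
#' @export
rank_term_from_place <- function(place, n_competitors) {
  if (any(n_competitors < 2)) {
    abort("`n_competitors` must be at least 2.",
          class = "spinpulse_error_validation")
  }
  if (any(place < 1 | place > n_competitors)) {
    abort("`place` must lie in [1, n_competitors].",
          class = "spinpulse_error_validation")
  }
  (n_competitors - place) / (n_competitors - 1)
}

#' Score trials from game results
#'
#' Computes the per-trial performance score
#' `100 * (kills / (kills + deaths) + rank_term)`. A trial with
#' `kills + deaths == 0` has an undefined kill ratio; instead of propagating
#' `NaN` it is flagged (`flatline = TRUE`, `performance = NA`) so the
#' participant-level exclusion screen can act on repeated flatlines.
#'
#' @param data Data frame with `kills`, `deaths` and either `rank_term` or
#'   both `place` and `n_competitors` columns.
#' @return `data` as a tibble with `performance` and `flatline` appended.
#' @export
#' @examples
#' trial_scores(tibble::tibble(kills = 10, deaths = 10, rank_term = 0.5))
trial_scores <- function(data) {
  data <- as_tibble(data)
  if (!"rank_term" %in% names(data)) {
    if (!all(c("place", "n_competitors") %in% names(data))) {
      abort("Need a `rank_term` column or both `place` and `n_competitors`.",
            class = "spinpulse_error_schema")
    }
    data$rank_term <- rank_term_from_place(data$place, data$n_competitors)
  }
  if (any(data$kills < 0 | data$deaths < 0, na.rm = TRUE)) {
    abort("`kills` and `deaths` must be nonnegative.",
          class = "spinpulse_error_validation")
  }
  if (any(data$rank_term < 0 | data$rank_term > 1, na.rm = TRUE)) {
    abort("`rank_term` must lie in [0, 1].",
          class = "spinpulse_error_validation")
  }
  data |>
    mutate(
      flatline = (.data$kills + .data$deaths) == 0,
      performance = ifelse(
        .data$flatline, NA_real_,
        100 * (.data$kills / (.data$kills + .data$deaths) + .data$rank_term)
      )
    )
}

#' Collapse trial pairs into session scores
#'
#' Averages consecutive trial pairs into session performance scores: trials
#' 1-2 form session 1, trials 3-4 session 2, and so on (28 trials become 14
#' sessions). A session containing any flatlined trial is itself flagged
#' `flatline` and its performance is the mean of the non-flagged trial scores
#' (or `NA` if both trials flatlined).
#'
#' @param data Trial-level data frame with `participant_id`, `trial_index`,
#'   `performance` and `flatline` columns (see [trial_scores()]).
#' @return Session-level tibble with `participant_id`, `session_index`,
#'   `performance`, `flatline`.
#' @export
collapse_sessions <- function(data) {
  data <- as_tibble(data)
  counts <- data |> count(.data$participant_id)
  odd <- counts$n %% 2 != 0
  if (any(odd)) {
    abort(
      paste0("Odd trial count for participant(s): ",
             paste(counts$participant_id[odd], collapse = ", ")),
      class = "spinpulse_error_structure"
    )
  }
  data |>
    arrange(.data$participant_id, .data$trial_index) |>
    group_by(.data$participant_id) |>
    mutate(session_index = (row_number() + 1L) %/% 2L) |>
    group_by(.data$participant_id, .data$session_index) |>
    summarise(
      performance = if (all(.data$flatline)) NA_real_ else
        mean(.data$performance[!.data$flatline]),
      flatline = any(.data$flatline),
      .groups = "drop"
    )
}

#' Participant exclusion screen
#'
#' Applies the participant-level data screens: a participant is dropped when
#' any expected session is missing (`incomplete`) or when the number of
#' flatlined sessions reaches `flatline_threshold` (`flatline`, default 2,
#' i.e. "repeated" flatlining). The screen is deterministic and independent
#' of row order.
#'
#' @param sessions Session-level data frame with `participant_id`,
#'   `session_index`, and optionally `flatline` and `performance` columns.
#' @param n_sessions_expected Number of sessions a complete record has.
#' @param flatline_threshold Minimum number of flatlined sessions that
#'   triggers exclusion.
#' @return A tibble with one row per participant: `participant_id`, `keep`
#'   (logical), `reason` (`"ok"`, `"incomplete"` or `"flatline"`),
#'   `n_sessions`, `n_flatline`.
#' @export
exclusion_screen <- function(sessions, n_sessions_expected = 14,
                             flatline_threshold = 2) {
  sessions <- as_tibble(sessions)
  if (!"flatline" %in% names(sessions)) sessions$flatline <- FALSE
  if (!"performance" %in% names(sessions)) sessions$performance <- 0
  sessions |>
    group_by(.data$participant_id) |>
    summarise(
      n_sessions = n_distinct(.data$session_index),
      n_flatline = sum(.data$flatline | is.na(.data$performance)),
      .groups = "drop"
    ) |>
    mutate(
      reason = case_when(
        n_sessions < n_sessions_expected ~ "incomplete",
        n_flatline >= flatline_threshold ~ "flatline",
        TRUE ~ "ok"
      ),
      keep = .data$reason == "ok"
    ) |>
    arrange(.data$participant_id)
}

#' Score session effort from the six-item scale
#'
#' Session effort is the arithmetic mean of the six 0-10 effort item
#' ratings.
#'
#' @param data Data frame containing the six item columns.
#' @param item_cols Character vector naming the six item columns.
#' @return `data` as a tibble with an `effort` column appended.
#' @export
#' @examples
#' d <- tibble::tibble(e1 = 0, e2 = 2, e3 = 4, e4 = 6, e5 = 8, e6 = 10)
#' score_effort(d, paste0("e", 1:6))$effort # 5
score_effort <- function(data, item_cols = paste0("effort_", 1:6)) {
  missing_cols <- setdiff(item_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing effort item column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spinpulse_error_schema")
  }
  if (length(item_cols) != 6) {
    abort("Effort scale has exactly 6 items.",
          class = "spinpulse_error_schema")
  }
  m <- as.matrix(data[item_cols])
  if (any(!is.na(m) & (m < 0 | m > 10))) {
    abort("Effort item ratings must lie in [0, 10].",
          class = "spinpulse_error_validation")
  }
  out <- as_tibble(data)
  out$effort <- rowMeans(m)
  out
}

#' Standardized video-game-experience composite
#'
#' Z-scores each of the four experience items within the cohort (two
#' frequency items and two hours-per-week items), averages each frequency /
#' hours pair, then averages the two pair means into one composite. By
#' construction the cohort mean of the composite is 0.
#'
#' @param data Person-level data frame.
#' @param freq_cols,hours_cols Character vectors (length 2 each) naming the
#'   frequency and hours item columns.
#' @param rescale If `TRUE` (default) the composite is additionally divided
#'   by its cohort SD so descriptives print as mean 0, SD 1.
#' @return `data` as a tibble with a `vge` column appended.
#' @export
vge_composite <- function(data,
                          freq_cols = c("vge_freq_any", "vge_freq_fps"),
                          hours_cols = c("vge_hours_any", "vge_hours_fps"),
                          rescale = TRUE) {
  cols <- c(freq_cols, hours_cols)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing experience item column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spinpulse_error_schema")
  }
  if (nrow(data) < 2) {
    abort("Standardizing needs at least 2 participants.",
          class = "spinpulse_error_insufficient_data")
  }
  z <- function(col) {
    x <- data[[col]]
    s <- sd(x)
    if (is.na(s) || s == 0) {
      abort(sprintf("Item `%s` has zero variance; cannot standardize.", col),
            class = "spinpulse_error_validation")
    }
    (x - mean(x)) / s
  }
  freq_mean <- (z(freq_cols[1]) + z(freq_cols[2])) / 2
  hours_mean <- (z(hours_cols[1]) + z(hours_cols[2])) / 2
  composite <- (freq_mean + hours_mean) / 2
  if (rescale) composite <- composite / sd(composite)
  out <- as_tibble(data)
  out$vge <- composite
  out
}
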