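#' Discontinuous growth time codes for a change-point design
#'
#' Builds the five change-variable codes used in discontinuous mixed-effects
#' growth models for `n_sessions` measurement occasions with an abrupt task
#' change after session `change_after`. For 1-based session `s`:
#'
#' * `SA`  (skill acquisition) = `s - 1`, the linear trend across all sessions;
#' * `TA`  (transition adaptation) = 1 after the change, else 0, the level
#'   discontinuity relative to the pre-change trajectory;
#' * `RA`  (reacquisition adaptation) = `max(0, s - change_after - 1)`, the
#'   post-change linear trend relative to the pre-change trend;
#' * `SA2` = `min(SA, change_after - 1)^2`, the quadratic acquisition code,
#'   capped at its pre-change maximum after the change;
#' * `RA2` = `RA^2`, the quadratic reacquisition code.
#'
#' The study default (14 sessions, change after 7) yields SA 0..13, TA
#' switching at session 8, RA 0..6 post-change, SA2 capped at 36, RA2 0..36.
#'
#' @param n_sessions Number of measurement occasions (>= 2).
#' @param change_after Session after which the task change occurs
#'   (in `[1, n_sessions - 1]`).
#' @return A tibble with columns `session_index`, `SA`, `TA`, `RA`, `SA2`,
#'   `RA2`.
#' @export
#' @examples
#' growth_design() # the 14-session / change-after-7 study design
growth_design <- function(n_sessions = 14, change_after = 7) {
  if (length(n_sessions) != 1 || n_sessions < 2 || n_sessions != round(n_sessions)) {
    abort("`n_sessions` must be a single integer >= 2.",
          class = "spinpulse_error_validation")
  }
  if (length(change_after) != 1 || change_after < 1 ||
      change_after >= n_sessions || change_after != round(change_after)) {
    abort("`change_after` must be a single integer in [1, n_sessions - 1].",
          class = "spinpulse_error_validation")
  }
  s <- seq_len(n_sessions)
  sa <- s - 1
  ra <- pmax(0, s - change_after - 1)
  tibble(
    session_index = as.integer(s),
    SA = as.numeric(sa),
    TA = as.numeric(s > change_after),
    RA = as.numeric(ra),
    SA2 = pmin(sa, change_after - 1)^2,
    RA2 = ra^2
  )
}

#' Attach growth time codes to a long table
#'
#' Joins the five design code columns onto a long participant-session table
#' by `session_index`. Re-attachment is idempotent: existing code columns are
#' replaced.
#'
#' @param data Long data frame with a `session_index` column.
#' @param design A design tibble from [growth_design()], or `NULL` to build
#'   one from `n_sessions`/`change_after`.
#' @param n_sessions,change_after Used when `design` is `NULL`.
#' @return `data` as a tibble with `SA`, `TA`, `RA`, `SA2`, `RA2` appended;
#'   row count and order unchanged.
#' @export
attach_design <- function(data, design = NULL, n_sessions = 14,
                          change_after = 7) {
  if (is.null(design)) design <- growth_design(n_sessions, change_after)
  if (!"session_index" %in% names(data)) {
    abort("`data` must have a `session_index` column.",
          class = "spinpulse_error_schema")
  }
  outside <- setdiff(unique(data$session_index), design$session_index)
  if (length(outside) > 0) {
    abort(
      paste0("session_index outside design range: ",
             paste(sort(outside), collapse = ", ")),
      class = "spinpulse_error_validation"
    )
  }
  code_cols <- c("SA", "TA", "RA", "SA2", "RA2")
  out <- as_tibble(data)
  out <- out[setdiff(names(out), code_cols)]
  left_join(out, design, by = "session_index")
}
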