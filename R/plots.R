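#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simple-slopes trajectories
#'
#' Draws the model-implied outcome trajectories at high and low moderator
#' levels produced by [simple_slopes()], with a dashed line at the task
#' change when the design codes make it identifiable.
#'
#' @param object A `spinpulse_slopes` tibble from [simple_slopes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spinpulse_slopes
#' @export
autoplot.spinpulse_slopes <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$session_index, y = .data$predicted,
    colour = .data$level, group = .data$level
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(
      x = "Session",
      y = paste("Predicted", attr(object, "outcome") %||% "outcome"),
      colour = paste0(attr(object, "moderator_name") %||% "moderator",
                      " (±1 SD)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed mean trajectories across sessions
#'
#' Cohort mean of an outcome per session with +-1 SE ribbons and a dashed
#' line at the task change.
#'
#' @param data Long data frame with `session_index` and the outcome column.
#' @param outcome Outcome column name (default `"performance"`).
#' @param change_after Session after which the task change occurred (for
#'   the reference line); `NULL` to omit.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, outcome = "performance",
                              change_after = 7) {
  summ <- data |>
    group_by(.data$session_index) |>
    summarise(
      mean = mean(.data[[outcome]], na.rm = TRUE),
      se = sd(.data[[outcome]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[outcome]]))),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$session_index,
                                          y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Session", y = paste("Mean", outcome)) +
    ggplot2::theme_minimal()
  if (!is.null(change_after)) {
    p <- p + ggplot2::geom_vline(xintercept = change_after + 0.5,
                                 linetype = "dashed")
  }
  p
}

#' Plot affect reports in the circumplex plane
#'
#' Scatter of (valence, activation) session reports, optionally coloured by
#' participant, with the neutral origin marked. Useful for eyeballing spin
#' (angular scatter) versus pulse (radial scatter).
#'
#' @param data Data frame with `valence` and `activation` columns.
#' @param colour_by Optional column name to colour points by (e.g.
#'   `"participant_id"`).
#' @return A ggplot object.
#' @export
plot_affect_space <- function(data, colour_by = NULL) {
  aes <- if (is.null(colour_by)) {
    ggplot2::aes(x = .data$valence, y = .data$activation)
  } else {
    ggplot2::aes(x = .data$valence, y = .data$activation,
                 colour = .data[[colour_by]])
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Valence", y = "Activation") +
    ggplot2::theme_minimal()
}
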