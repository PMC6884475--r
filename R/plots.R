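#' Learning-curve plot of the driving-performance metrics
#'
#' Mean and standard error of SDLP and SWV per condition across the trial
#' sequence (pretest, training, posttest), the standard summary figure for
#' this paradigm.
#'
#' @param metrics A metrics table from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(metrics) {
  d <- metrics |>
    tidyr::pivot_longer(c("sdlp", "swv"), names_to = "metric") |>
    dplyr::mutate(
      session = factor(.data$session,
                       levels = c("pretest", "training", "posttest")),
      metric = toupper(.data$metric)
    ) |>
    dplyr::group_by(.data$group, .data$session, .data$trial, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$mean,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(metric ~ session, scales = "free",
                        space = "free_x") +
    ggplot2::labs(x = "trial", y = NULL, colour = "condition",
                  fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot one trial's lateral deviation and steering trace
#'
#' Deviation from the lane centre and steering-wheel angle over time, with
#' curve-negotiation windows shaded.
#'
#' @param log A `trial_log` from [simulate_trial()].
#' @param course Optional `road_course` for window detection (defaults to
#'   the log's `segment_kind` column).
#' @return A ggplot object.
#' @export
plot_trial <- function(log, course = NULL) {
  w <- curve_windows(log, course)
  d <- tibble::tibble(
    t = rep(log$t, 2),
    value = c(log$deviation, log$sw_angle),
    series = rep(c("lateral deviation (m)", "steering angle (rad)"),
                 each = nrow(log))
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value))
  if (nrow(w) > 0) {
    p <- p + ggplot2::geom_rect(
      data = w,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.lk_experiment <- function(object, ...) {
  plot_learning_curves(object$metrics)
}
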