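#' Plot an equal-pitch curve
#'
#' @param object An [equal_pitch_curve()].
#' @param ... Unused.
#' @return A ggplot: frequency against amplitude on log-log axes, with the
#'   reference stimulus marked.
#' @export
autoplot.equal_pitch_curve <- function(object, ...) {
  ref <- tibble(
    amplitude_um = attr(object, "ref_amplitude_um"),
    frequency_hz = attr(object, "ref_frequency_hz")
  )
  ggplot2::ggplot(object, ggplot2::aes(.data$amplitude_um, .data$frequency_hz)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = ref, shape = 15, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Amplitude (µm)", y = "Frequency (Hz)",
      title = sprintf("Equal-pitch curve, k = %.3g", attr(object, "k"))
    )
}

#' Plot a fitted psychometric function with its binned data
#'
#' @param object A [fit_psychometric()] object.
#' @param n_grid Number of curve evaluation points (default 200).
#' @param ... Unused.
#' @return A ggplot of response fraction against stimulus level.
#' @export
autoplot.psychometric_fit <- function(object, n_grid = 200L, ...) {
  d <- object$data
  grid <- tibble(level = seq(min(d$level), max(d$level), length.out = n_grid))
  grid$p <- predict(object, grid$level)
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$n_chosen / .data$n_total)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$level, .data$p),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mu, linetype = "dashed") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "Stimulus level", y = "Response fraction",
                  title = sprintf("PSE = %.4g", object$mu))
}

#' Plot shift-ratio data with the fitted equal-pitch curve
#'
#' @param object An `equal_pitch_overlay` from [equal_pitch_points()].
#' @param ... Unused.
#' @return A ggplot in stimulus space (amplitude vs frequency).
#' @export
autoplot.equal_pitch_overlay <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::geom_point(data = object$points, colour = "grey30")
}

#' Plot an aggregated V-shaped sensitivity curve
#'
#' @param object A [aggregate_sensitivity()] result.
#' @param ... Unused.
#' @return A ggplot of mean threshold (with SEM) against frequency, log-log.
#' @export
autoplot.sensitivity_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$mean_threshold)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_threshold - .data$sem,
                                        ymax = .data$mean_threshold + .data$sem),
                           width = 0.02) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "best_frequency_interp"),
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Detection threshold (µm)",
                  title = "V-shaped sensitivity curve")
}

#' Plot a staircase trace from a session table
#'
#' @param data A session table from a staircase-driven task (columns `delta`
#'   or `amplitude_um` over `trial_index`).
#' @param y Which quantity to trace: `"delta"` (frequency/amplitude difference)
#'   or `"amplitude"`.
#' @return A ggplot of the adaptive track over trials.
#' @export
plot_staircase <- function(data, y = c("delta", "amplitude")) {
  y <- match.arg(y)
  col <- if (y == "delta") "delta" else "amplitude_um"
  if (!col %in% names(data)) {
    abort(sprintf("Column `%s` not found in the session table.", col),
          class = "vibropitch_schema_error")
  }
  mapping <- if ("side" %in% names(data)) {
    ggplot2::aes(.data$trial_index, .data[[col]], colour = .data$side)
  } else {
    ggplot2::aes(.data$trial_index, .data[[col]])
  }
  ggplot2::ggplot(data, mapping) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct), size = 1.5) +
    ggplot2::labs(x = "Trial", y = col)
}
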