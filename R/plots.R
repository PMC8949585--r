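#' Plot a predicted performance trajectory
#'
#' Draws the predicted performance (solid line) with its fitness (baseline +
#' fitness, dashed) and fatigue (baseline - fatigue, dashed) components, and
#' the daily TRIMPs as columns rescaled to the performance axis.
#'
#' @param object A `banister_trajectory` from [predict_performance()].
#' @param trimp_scale Height of the tallest TRIMP column as a fraction of the
#'   performance range (default 0.25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot banister_trajectory
#' @export
autoplot.banister_trajectory <- function(object, trimp_scale = 0.25, ...) {
  p0 <- object$predicted[1]
  long <- tibble::tibble(
    day = rep(object$day, 3),
    value = c(object$predicted, p0 + object$fitness, p0 - object$fatigue),
    component = rep(c("predicted", "fitness", "fatigue"), each = nrow(object))
  )
  rng <- range(long$value)
  w_max <- max(object$trimp, 1e-9)
  bars <- tibble::tibble(
    day = object$day,
    top = rng[1] + object$trimp / w_max * trimp_scale * diff(rng)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_col(
      data = bars, ggplot2::aes(y = .data$top - rng[1]),
      position = ggplot2::position_nudge(y = rng[1]),
      fill = "grey70", width = 1
    ) +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$value, colour = .data$component, linetype = .data$component
    )) +
    ggplot2::scale_colour_manual(values = c(
      predicted = "#2c5aa0", fitness = "#2e8b57", fatigue = "#b22222"
    )) +
    ggplot2::scale_linetype_manual(values = c(
      predicted = "solid", fitness = "dashed", fatigue = "dashed"
    )) +
    ggplot2::labs(
      x = "Day", y = "Performance (m)",
      colour = NULL, linetype = NULL,
      title = "Fitness-fatigue impulse-response trajectory",
      subtitle = "Grey columns: daily TRIMP (rescaled)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Banister fit with its visit measurements
#'
#' @param object A `banister_fit` from [fit_banister()].
#' @param trimp_scale Passed to [autoplot.banister_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot banister_fit
#' @export
autoplot.banister_fit <- function(object, trimp_scale = 0.25, ...) {
  traj <- predict_performance(object$params, object$trimp,
                              horizon = max(object$fitted$day, length(object$trimp)))
  autoplot.banister_trajectory(traj, trimp_scale = trimp_scale) +
    ggplot2::geom_point(
      data = object$fitted,
      ggplot2::aes(x = .data$day, y = .data$measured),
      colour = "#e07b00", shape = 18, size = 3
    )
}

#' Plot a Passing-Bablok regression
#'
#' Scatter of the paired values with the identity line (dotted) and the
#' fitted Passing-Bablok line (solid).
#'
#' @param object A `passing_bablok` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot passing_bablok
#' @export
autoplot.passing_bablok <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "#2c5aa0"
    ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Measured (m)", y = "Estimated (m)",
      title = "Passing-Bablok method comparison",
      subtitle = sprintf(
        "slope %.2f [%.2f, %.2f], intercept %.1f [%.1f, %.1f]",
        object$slope, object$ci_slope[1], object$ci_slope[2],
        object$intercept, object$ci_intercept[1], object$ci_intercept[2]
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
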