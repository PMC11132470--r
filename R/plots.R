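#' Plot a modulation spectrum
#'
#' @param object A [spectrum_curve()].
#' @param compensate Show the 1/f-compensated spectrum (`power * freq`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_curve
#' @export
autoplot.spectrum_curve <- function(object, compensate = FALSE, ...) {
  d <- tibble::as_tibble(object)
  if (compensate) d$power <- d$power * d$freq
  ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Modulation frequency (Hz)",
                  y = if (compensate) "Compensated power" else "Power") +
    ggplot2::theme_minimal()
}

#' Plot per-participant psychometric fits
#'
#' Shows each participant's fitted linear psychometric function over the
#' tested range, the classic spaghetti view of slope heterogeneity.
#'
#' @param object A [fit_psychometric()] table.
#' @param x_range Range of the manipulated parameter to draw over.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psychometric_fits
#' @export
autoplot.psychometric_fits <- function(object, x_range = c(0.6, 6), ...) {
  d <- tidyr::expand_grid(tibble::as_tibble(object),
                          x = seq(x_range[1], x_range[2], length.out = 2))
  d$y <- d$intercept + d$slope * d$x
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                       group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Stimulus level", y = "P(response = 1)") +
    ggplot2::theme_minimal()
  extra <- intersect(c("task", "m_hz"), names(object))
  if (length(extra)) p <- p + ggplot2::facet_wrap(extra[1])
  p
}

#' Plot mean response per stimulus level
#'
#' @param responses A trial-level response table (testing trials are used).
#' @return A ggplot of the group mean response (+/- SE) per level.
#' @export
plot_mean_responses <- function(responses) {
  d <- responses |>
    dplyr::filter(.data$kind == "testing") |>
    dplyr::group_by(.data$participant_id, .data$x_value) |>
    dplyr::summarise(p = mean(.data$response), .groups = "drop") |>
    dplyr::group_by(.data$x_value) |>
    dplyr::summarise(mean_p = mean(.data$p),
                     se = sd(.data$p) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$x_value, .data$mean_p)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_p - .data$se,
                                          ymax = .data$mean_p + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Stimulus level", y = "Mean P(response = 1)") +
    ggplot2::theme_minimal()
}

#' Plot the slope distribution of a fitted experiment
#'
#' @param fits A [fit_psychometric()] table.
#' @return A ggplot: per-participant slopes with the group mean +/- SE.
#' @export
plot_slopes <- function(fits) {
  extra <- intersect(c("task", "m_hz"), names(fits))
  d <- tibble::as_tibble(fits)
  d$group <- if (length(extra)) factor(d[[extra[1]]]) else factor("all")
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$slope)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, color = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Response slope") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
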