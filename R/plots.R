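#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sampled signal
#'
#' @param object A [sampled_signal()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method autoplot
autoplot.sampled_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c5f8a") +
    ggplot2::labs(
      x = "time (s)",
      y = if (nzchar(sig_units(object))) sig_units(object) else "value",
      title = attr(object, "label") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a wave-separation result
#'
#' Pulsatile pressure with its forward and backward components.
#'
#' @param object A `wave_separation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method autoplot
autoplot.wave_separation <- function(object, ...) {
  d <- object$waves |>
    tidyr::pivot_longer(c("dp", "pf", "pb"), names_to = "wave",
                        values_to = "pressure") |>
    dplyr::mutate(wave = factor(.data$wave, levels = c("dp", "pf", "pb"),
                                labels = c("pulsatile P", "forward (Pf)",
                                           "backward (Pb)")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$pressure,
                                  colour = .data$wave)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL,
                  subtitle = sprintf("Zc = %.3g mmHg s/mL, RIx = %.2f",
                                     object$zc, object$reflection_index)) +
    ggplot2::theme_minimal()
}

#' Plot a CVR session summary
#'
#' Per-repeat velocity responses against end-tidal rises; the slope of the
#' origin line is the absolute reactivity.
#'
#' @param object A `cvr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method autoplot
autoplot.cvr_result <- function(object, ...) {
  ggplot2::ggplot(object$per_repeat,
                  ggplot2::aes(x = .data$delta_etco2, y = .data$delta_mcav,
                               shape = .data$valid)) +
    ggplot2::geom_abline(slope = object$cvr_abs, intercept = 0,
                         linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 3, colour = "#2c5f8a") +
    ggplot2::labs(x = expression(Delta * "ETCO2 (mmHg)"),
                  y = expression(Delta * "MCAv (cm/s)"),
                  subtitle = sprintf("CVR = %.2f cm/s/mmHg", object$cvr_abs)) +
    ggplot2::theme_minimal()
}

#' Group-by-time means for one outcome
#'
#' The standard interaction plot behind a 2x3 repeated-measures analysis:
#' cell means with SD error bars by group across time.
#'
#' @param table Long study table (`subject`, `group`, `time`, `outcome`,
#'   `value`).
#' @param outcome Outcome to plot.
#' @return A ggplot.
#' @export
plot_group_time <- function(table, outcome) {
  d <- table |>
    dplyr::filter(.data$outcome == !!outcome) |>
    dplyr::group_by(.data$group, .data$time) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$mean,
                                  group = .data$group,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = NULL, y = outcome, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
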