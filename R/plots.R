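#' Plot a shift function
#'
#' Decile differences (first minus second sample) against the first
#' sample's deciles, with the simultaneous bootstrap confidence interval at
#' each decile; positive differences in orange, negative in purple, and a
#' dashed zero line.
#'
#' @param shift A `shift_result` from [shift_function()].
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_shift_function <- function(shift, xlab = "group 1 deciles",
                                ylab = "difference (group 1 - group 2)") {
  ggplot2::ggplot(shift, ggplot2::aes(x = .data$q_x, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$difference >= 0),
                        size = 2.5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#E69F00",
                                            `FALSE` = "#7B68AE")) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shift_result <- function(object, ...) plot_shift_function(object, ...)

#' Stripchart of a subject-level measure by group
#'
#' Jittered per-subject values by group with Harrell-Davis deciles overlaid
#' as vertical bars (the median drawn heavier), the companion view to a
#' shift function.
#'
#' @param data Data frame. @param value,group Column names (strings).
#' @return A ggplot object.
#' @export
plot_group_stripchart <- function(data, value, group = "sex") {
  dec <- data |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::summarise(q = hd_quantile(.data[[value]], seq(0.1, 0.9, 0.1)),
                     decile = seq(0.1, 0.9, 0.1), .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[value]],
                                     y = .data[[group]])) +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.5, size = 1.5) +
    ggplot2::geom_point(data = dec,
                        ggplot2::aes(x = .data$q, y = .data[[group]],
                                     size = .data$decile == 0.5),
                        shape = "|", colour = "black", show.legend = FALSE) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 8, `FALSE` = 5)) +
    ggplot2::labs(x = value, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a weighted alpha-power profile
#'
#' Time course of the channel-weighted alpha-band power with the frequency
#' of the per-time maximum highlighted; analysis windows shaded.
#'
#' @param weighted Output of [weighted_alpha_power()].
#' @return A ggplot object.
#' @export
plot_weighted_alpha <- function(weighted) {
  freqs <- attr(weighted, "freqs")
  times <- attr(weighted, "times")
  df <- tidyr::expand_grid(freq = freqs, time = times)
  df$power <- as.vector(weighted)
  wins <- analysis_windows()
  win_df <- tibble::tibble(window = names(wins),
                           start = vapply(wins, `[`, 0, 1),
                           end = vapply(wins, `[`, 0, 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(data = win_df,
                        ggplot2::aes(xintercept = .data$start),
                        linetype = "dotted") +
    ggplot2::scale_fill_viridis_c(name = expression(power ~ (mu * V^2))) +
    ggplot2::labs(x = "time (s, cue onset = 0)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
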