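# ggplot2 autoplot methods for the main result containers.

#' Plot a time-frequency power matrix
#'
#' Raster of (optionally log-scaled) wavelet power over time and frequency.
#'
#' @param object A `tg_tfr` from [wavelet_power()] or [theta_triggered_tfr()].
#' @param log10_power Plot `log10(power)` instead of raw power.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_tfr <- function(object, log10_power = TRUE, ...) {
  df <- tidy(object)
  if (log10_power) {
    df$power <- log10(pmax(df$power, .Machine$double.xmin))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (log10_power) "log10 power" else "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a state segmentation
#'
#' Bin-wise theta/slow labels with the theta:slow power ratio.
#'
#' @param object A `tg_state_segmentation` from [segment_states()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_state_segmentation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_s, y = .data$ratio,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = attr(object, "bin_len") / attr(object, "fs")) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "theta / slow power ratio",
                  fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot a phase histogram
#'
#' Normalized event fractions over the 30-degree phase bins (peak of the
#' reference oscillation at 0 degrees).
#'
#' @param object A `tg_phase_histogram` from [phase_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_phase_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fraction)) +
    ggplot2::geom_col(width = attr(object, "bin_deg") * 0.9,
                      fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 90)) +
    ggplot2::labs(x = "phase (deg, peak = 0)", y = "fraction of events") +
    ggplot2::theme_minimal()
}
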