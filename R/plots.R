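# ggplot2 visualizations for the main result types.

#' @describeIn epoch_average Plot the trial-averaged waveform with a
#'   standard-error ribbon.
#' @param object An [epoch_matrix()].
#' @param ... Unused.
#' @export
autoplot.epoch_matrix <- function(object, ...) {
  df <- epoch_average(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "orange") +
    ggplot2::labs(x = "time from stimulus (s)", y = "amplitude",
                  title = sprintf("trial average (n = %d)",
                                  nrow(object$data)))
}

#' @describeIn spike_density Plot the peristimulus rate curve with the
#'   baseline band (2 and 3 SD).
#' @param object A `rate_curve`.
#' @param ... Unused.
#' @export
autoplot.rate_curve <- function(object, ...) {
  df <- as_tibble(object)
  bm <- object$baseline_mean
  bs <- max(object$baseline_sd, 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time, y = .data$rate)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = bm - 3 * bs, ymax = bm + 3 * bs,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = bm - 2 * bs, ymax = bm + 2 * bs,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = bm, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "orange") +
    ggplot2::labs(x = "time from stimulus (s)", y = "rate (spikes/s)",
                  title = sprintf("spike density (n = %d trials)",
                                  object$n_trials))
}

#' @describeIn multitaper_psd Plot the PSD on a log power scale.
#' @param object A `psd_estimate`.
#' @param bands Optional [band_set()] to shade.
#' @param ... Unused.
#' @export
autoplot.psd_estimate <- function(object, bands = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$power))
  if (!is.null(bands)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(bands),
      ggplot2::aes(xmin = .data$lo_hz, xmax = .data$hi_hz,
                   ymin = -Inf, ymax = Inf, fill = .data$band),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (units²/Hz)")
}

#' Plot state-wise band powers from a staging comparison
#'
#' @param powers The window-by-band power tibble from
#'   `state_window_powers()` or a [compare_states()] result joined with it;
#'   must have columns `state`, `band`, `power`.
#' @return A ggplot object (boxplots of log band power per state).
#' @export
plot_band_powers <- function(powers) {
  ggplot2::ggplot(powers, ggplot2::aes(x = .data$band, y = .data$power,
                                       fill = .data$state)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "band power", fill = "state")
}
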