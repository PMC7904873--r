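#' Residual orthogonality test for an evoked local field potential
#'
#' Detects a stimulus-locked component shared across trials. After per-trial
#' linear detrending ([detrend_trials()]), the statistic is formed from the
#' point-to-point product-sums of every unordered trial pair,
#' `s_ij = sum_t x_i(t) x_j(t)` for `i < j`. A response waveform common to
#' the trials shifts every pair sum by its squared norm, so the mean of the
#' pair sums is positive in its presence and scattered around zero for
#' trial-incoherent fluctuations. The mean is compared to zero with a
#' one-sample t test; a site-state is called responsive when the mean is
#' positive and the one-sided p-value falls below `alpha`. The pairwise sums
#' are treated as exchangeable observations (they are uncorrelated, though
#' not independent, under the no-response null); both one- and two-sided
#' p-values are reported.
#'
#' @param epochs An [epoch_matrix()] of raw (not yet detrended) trials.
#' @param window Analysis window in relative seconds, default
#'   `c(0.040, 0.540)`: 500 ms starting 40 ms after stimulus onset, skipping
#'   the stimulation-artifact blanking.
#' @param alpha Detection level (default 0.05).
#' @param detrend Set `FALSE` if `epochs` are already detrended/windowed.
#' @return An object of class `rot_result` with fields `n_trials`, `n_pairs`,
#'   `pair_mean` (and `pair_mean_per_sample`), `t_stat`, `p_value`
#'   (one-sided), `p_two_sided`, `responsive`, `window`.
#' @examples
#' hyp <- gen_hypnogram("SWS", 120)
#' ev <- gen_stim_times(hyp, c(10, 12), seed = 1)
#' rec <- gen_lfp_evoked(hyp, ev, evoked_spec(amplitude = 5), rate = 500,
#'                       seed = 1)
#' ep <- extract_epochs(rec, ev, c(0.5, 0.6))
#' rot_test(ep)
#' @export
rot_test <- function(epochs, window = c(0.040, 0.540), alpha = 0.05,
                     detrend = TRUE) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  if (nrow(epochs$data) < 3L) {
    stop_evoked("evoked_insufficient",
                "residual orthogonality test needs at least 3 trials")
  }
  wd <- if (detrend) detrend_trials(epochs, window) else epochs
  X <- wd$data
  if (any(apply(X, 1L, function(r) all(r == 0)))) {
    stop_evoked("evoked_degenerate", "zero-variance trial in test window")
  }
  n <- nrow(X)
  G <- tcrossprod(X)                      # s_ij in the off-diagonal
  pairs <- G[upper.tri(G)]
  np <- n * (n - 1L) / 2L
  tt <- t.test(pairs, mu = 0)
  t_stat <- unname(tt$statistic)
  p_one <- pt(t_stat, df = np - 1L, lower.tail = FALSE)
  structure(
    list(n_trials = n, n_pairs = np, pair_mean = mean(pairs),
         pair_mean_per_sample = mean(pairs) / ncol(X),
         t_stat = t_stat, p_value = p_one, p_two_sided = unname(tt$p.value),
         responsive = mean(pairs) > 0 && p_one < alpha,
         alpha = alpha, window = window),
    class = "rot_result"
  )
}

#' @export
print.rot_result <- function(x, ...) {
  cat(sprintf(
    "<rot_result> %d trials (%d pairs), window [%g, %g) s\n  pair mean %.4g (%.4g / sample), t = %.3f, one-sided p = %.4g -> %s\n",
    x$n_trials, x$n_pairs, x$window[1], x$window[2], x$pair_mean,
    x$pair_mean_per_sample, x$t_stat, x$p_value,
    if (x$responsive) "responsive" else "not responsive"))
  invisible(x)
}

#' @export
tidy.rot_result <- function(x, ...) {
  tibble(n_trials = x$n_trials, n_pairs = x$n_pairs, pair_mean = x$pair_mean,
         pair_mean_per_sample = x$pair_mean_per_sample, t_stat = x$t_stat,
         p_value = x$p_value, p_two_sided = x$p_two_sided,
         responsive = x$responsive)
}

#' @export
glance.rot_result <- function(x, ...) tidy(x)

#' Compare evoked-response peak amplitude between sleep and wakefulness
#'
#' For each state the trial-averaged z-scored signal is searched for its
#' absolute extremum inside the analysis window; each trial is then averaged
#' over the 40 ms window centered on that extremum, and the two per-trial
#' samples are compared with the Wilcoxon rank-sum test. Intended for
#' site-states where an evoked potential was already detected ([rot_test()]);
#' inputs must be z-scored to the pre-stimulus baseline
#' ([zscore_to_baseline()]) so that state differences in background LFP
#' amplitude (e.g. sleep delta waves) do not masquerade as response
#' differences.
#'
#' @param z_sleep,z_wake Z-scored [epoch_matrix()] objects for the two
#'   states.
#' @param window Analysis window, default `c(0.040, 0.540)` s.
#' @param peak_halfwidth_s Half of the peak-averaging window (default 0.020,
#'   i.e. a 40 ms window).
#' @param alpha Significance level for assigning a direction.
#' @return An object of class `amplitude_comparison` with per-state peak
#'   times, per-trial mean amplitudes, the rank-sum `p_value` and
#'   `direction` (`"sleep_larger"`, `"wake_larger"` or `"none"`).
#' @export
compare_peak_amplitude <- function(z_sleep, z_wake, window = c(0.040, 0.540),
                                   peak_halfwidth_s = 0.020, alpha = 0.05) {
  peak_of <- function(ep) {
    sel <- ep$rel_time >= window[1] & ep$rel_time < window[2]
    if (!any(sel)) stop_evoked("evoked_invalid_window",
                               "analysis window outside rel_time")
    avg <- colMeans(ep$data[, sel, drop = FALSE])
    tpk <- ep$rel_time[sel][which.max(abs(avg))]
    w0 <- tpk - peak_halfwidth_s
    w1 <- tpk + peak_halfwidth_s
    clipped <- FALSE
    if (w0 < window[1]) { w0 <- window[1]; clipped <- TRUE }
    if (w1 > window[2]) { w1 <- window[2]; clipped <- TRUE }
    wsel <- ep$rel_time >= w0 & ep$rel_time < w1
    tm <- rowMeans(ep$data[, wsel, drop = FALSE])
    # orient each trial's amplitude along the state's own response polarity,
    # so negative-going responses compare on equal footing
    list(peak_time = tpk, trial_means = tm * sign(avg[which.max(abs(avg))]),
         clipped = clipped)
  }
  ps <- peak_of(z_sleep)
  pw <- peak_of(z_wake)
  wt <- suppressWarnings(wilcox.test(ps$trial_means, pw$trial_means))
  direction <- "none"
  if (is.finite(wt$p.value) && wt$p.value < alpha) {
    direction <- if (median(ps$trial_means) > median(pw$trial_means))
      "sleep_larger" else "wake_larger"
  }
  structure(
    list(peak_time_s = c(sleep = ps$peak_time, wake = pw$peak_time),
         trial_means = list(sleep = ps$trial_means, wake = pw$trial_means),
         peak_window_clipped = c(sleep = ps$clipped, wake = pw$clipped),
         p_value = unname(wt$p.value), direction = direction, alpha = alpha),
    class = "amplitude_comparison"
  )
}

#' @export
print.amplitude_comparison <- function(x, ...) {
  cat(sprintf(
    "<amplitude_comparison> peaks at %.3f s (sleep) / %.3f s (wake); rank-sum p = %.4g -> %s\n",
    x$peak_time_s[["sleep"]], x$peak_time_s[["wake"]], x$p_value, x$direction))
  invisible(x)
}

#' @export
tidy.amplitude_comparison <- function(x, ...) {
  tibble(peak_time_sleep_s = x$peak_time_s[["sleep"]],
         peak_time_wake_s = x$peak_time_s[["wake"]],
         median_amp_sleep = median(x$trial_means$sleep),
         median_amp_wake = median(x$trial_means$wake),
         p_value = x$p_value, direction = x$direction)
}
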