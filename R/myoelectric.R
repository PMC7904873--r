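#' Analysis windows and bands for duodenal myoelectric responses
#'
#' @param simple_band Simple-wave (electrical control activity) band in Hz,
#'   default `c(0, 2)`.
#' @param burst_band Spike-potential (electrical response activity) band,
#'   default `c(3, 10)` Hz.
#' @param pre_post_s Length of the simple-wave comparison windows (40 s).
#' @param post_offset_s Delay of the post-stimulus window after onset
#'   (0.5 s).
#' @param burst_window_s Length of the spike-potential window (20 s),
#'   centered at the simple-wave modulation extremum.
#' @param envelope_smooth_s Moving-average width for the modulation
#'   envelope (5 s).
#' @return A list of class `myo_windows`.
#' @export
myo_windows <- function(simple_band = c(0, 2), burst_band = c(3, 10),
                        pre_post_s = 40, post_offset_s = 0.5,
                        burst_window_s = 20, envelope_smooth_s = 5) {
  if (simple_band[2] <= simple_band[1] || burst_band[2] <= burst_band[1] ||
      simple_band[2] > burst_band[1]) {
    stop_evoked("evoked_invalid_band", "bands must be ordered and disjoint")
  }
  if (pre_post_s <= 0 || burst_window_s <= 0) {
    stop_evoked("evoked_invalid_window", "windows must be positive")
  }
  structure(
    list(simple_band = simple_band, burst_band = burst_band,
         pre_post_s = pre_post_s, post_offset_s = post_offset_s,
         burst_window_s = burst_window_s,
         envelope_smooth_s = envelope_smooth_s),
    class = "myo_windows"
  )
}

# Events usable for the 40 s pre/post comparison (windows inside recording
# and, when a hypnogram is given, inside a single interval of `state`).
usable_myo_events <- function(rec, events, cfg, hyp = NULL, state = NULL) {
  onsets <- events$onset_s[!events$artifact]
  keep <- vapply(onsets, function(on) {
    if (on - cfg$pre_post_s < rec$start_time) return(FALSE)
    if (on + cfg$post_offset_s + cfg$pre_post_s > rec_end(rec)) return(FALSE)
    if (!is.null(hyp)) {
      st <- span_state(hyp, on - cfg$pre_post_s,
                       on + cfg$post_offset_s + cfg$pre_post_s)
      if (is.na(st) || st == "state_change") return(FALSE)
      if (!is.null(state) && st != state) return(FALSE)
    }
    TRUE
  }, logical(1))
  onsets[keep]
}

#' Stimulus-locked change of simple-wave (0-2 Hz) power
#'
#' Per event, multitaper band power of the gut signal in the 40 s before
#' onset and the 40 s starting 0.5 s after onset; the paired powers are
#' compared across events with the Wilcoxon signed-rank test, and a
#' direction is assigned from the median paired difference when `p < alpha`.
#'
#' @param rec A gut [cont_rec()].
#' @param events An [event_series()].
#' @param cfg A [myo_windows()].
#' @param hyp Optional [hypnogram()]; with `state`, restricts events to
#'   those fully inside one interval of that state.
#' @param state Optional state filter.
#' @param NW,K Multitaper parameters (reused from the EEG analysis).
#' @param alpha Significance level.
#' @return A list of class `myo_band_result`: `n_events`, `p_value`,
#'   `direction` (`"increase"`/`"decrease"`/`"none"`), `powers` (tibble with
#'   per-event `pre` and `post`).
#' @export
simple_wave_response <- function(rec, events, cfg = myo_windows(),
                                 hyp = NULL, state = NULL, NW = 3, K = 5L,
                                 alpha = 0.05) {
  onsets <- usable_myo_events(rec, events, cfg, hyp, state)
  if (length(onsets) < 6L) {
    stop_evoked("evoked_insufficient",
                sprintf("only %d usable events (need >= 6)", length(onsets)))
  }
  pre <- post <- numeric(length(onsets))
  for (j in seq_along(onsets)) {
    on <- onsets[j]
    pre[j] <- band_power(multitaper_psd(
      rec_slice(rec, on - cfg$pre_post_s, on), NW, K), cfg$simple_band)
    post[j] <- band_power(multitaper_psd(
      rec_slice(rec, on + cfg$post_offset_s,
                on + cfg$post_offset_s + cfg$pre_post_s), NW, K),
      cfg$simple_band)
  }
  wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
  dir <- "none"
  if (wt$p.value < alpha) {
    dir <- if (median(post - pre) > 0) "increase" else "decrease"
  }
  structure(
    list(n_events = length(onsets), p_value = wt$p.value, direction = dir,
         powers = tibble(onset_s = onsets, pre = pre, post = post),
         band = cfg$simple_band, alpha = alpha),
    class = "myo_band_result"
  )
}

#' @export
print.myo_band_result <- function(x, ...) {
  cat(sprintf(
    "<myo_band_result> band [%g, %g] Hz, %d events: signed-rank p = %.4g -> %s\n",
    x$band[1], x$band[2], x$n_events, x$p_value, x$direction))
  invisible(x)
}

#' @export
tidy.myo_band_result <- function(x, ...) {
  tibble(band_lo_hz = x$band[1], band_hi_hz = x$band[2],
         n_events = x$n_events, p_value = x$p_value, direction = x$direction)
}

#' Time of the post-stimulus simple-wave modulation extremum
#'
#' Band-limits the post-stimulus window to the simple-wave band, forms the
#' amplitude envelope (magnitude of the analytic signal, smoothed with a 5 s
#' moving average) and returns the time of its maximum relative to the
#' stimulus onset — or of its minimum when the session's simple-wave power
#' change was a decrease.
#'
#' @param rec A gut [cont_rec()].
#' @param event_onset One stimulus onset time in seconds.
#' @param cfg A [myo_windows()].
#' @param direction `"increase"` (default; envelope maximum) or
#'   `"decrease"` (envelope minimum), typically the session-level direction
#'   from [simple_wave_response()].
#' @return Extremum time in seconds relative to onset. Attribute
#'   `degenerate` is `TRUE` when the in-band envelope is essentially flat
#'   at zero.
#' @export
modulation_extremum <- function(rec, event_onset, cfg = myo_windows(),
                                direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  t0 <- event_onset + cfg$post_offset_s
  t1 <- t0 + cfg$pre_post_s
  if (t0 < rec$start_time || t1 > rec_end(rec)) {
    stop_evoked("evoked_invalid_window", "post-stimulus window truncated")
  }
  seg <- rec_slice(rec, t0, t1)
  lo <- max(cfg$simple_band[1], 0)
  env <- band_envelope(seg, lo, cfg$simple_band[2],
                       smooth_s = cfg$envelope_smooth_s)
  degenerate <- max(env$samples) < 1e-10
  idx <- if (direction == "increase") which.max(env$samples)
         else which.min(env$samples)
  out <- (idx - 1L) / rec$rate + cfg$post_offset_s
  attr(out, "degenerate") <- degenerate
  out
}

#' Stimulus-locked change of spike-potential (3-10 Hz) power
#'
#' For each event with modulation extremum at `+T` (clamped so the 20 s
#' window stays post-stimulus, i.e. `T >= post_offset_s + 10`), compares
#' burst-band power in `[T - 10, T + 10)` after onset against the
#' time-mirrored window `[-T - 10, -T + 10)` before onset, with a paired
#' signed-rank test across events. Events whose mirrored pre-window leaves
#' the recording are dropped and counted.
#'
#' @param rec A gut [cont_rec()].
#' @param events An [event_series()].
#' @param extrema Extremum times relative to onset, one per non-flagged
#'   event (from [modulation_extremum()]); recycled if length 1.
#' @param cfg A [myo_windows()].
#' @param NW,K Multitaper parameters.
#' @param alpha Significance level.
#' @return A `myo_band_result` (see [simple_wave_response()]) with
#'   additional fields `extrema_s`, `n_clamped`, `n_dropped`.
#' @export
spike_potential_response <- function(rec, events, extrema,
                                     cfg = myo_windows(), NW = 3, K = 5L,
                                     alpha = 0.05) {
  onsets <- events$onset_s[!events$artifact]
  extrema <- rep_len(as.numeric(extrema), length(onsets))
  half <- cfg$burst_window_s / 2
  tmin <- cfg$post_offset_s + half
  clamped <- extrema < tmin
  extrema[clamped] <- tmin
  pre <- post <- numeric(0)
  used_on <- used_T <- numeric(0)
  dropped <- 0L
  for (j in seq_along(onsets)) {
    on <- onsets[j]; Tm <- extrema[j]
    ok <- on - Tm - half >= rec$start_time &&
      on + Tm + half <= rec_end(rec)
    if (!ok) { dropped <- dropped + 1L; next }
    post_p <- band_power(multitaper_psd(
      rec_slice(rec, on + Tm - half, on + Tm + half), NW, K), cfg$burst_band)
    pre_p <- band_power(multitaper_psd(
      rec_slice(rec, on - Tm - half, on - Tm + half), NW, K), cfg$burst_band)
    pre <- c(pre, pre_p); post <- c(post, post_p)
    used_on <- c(used_on, on); used_T <- c(used_T, Tm)
  }
  if (length(pre) < 6L) {
    stop_evoked("evoked_insufficient",
                sprintf("only %d usable events (need >= 6)", length(pre)))
  }
  wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
  dir <- "none"
  if (wt$p.value < alpha) {
    dir <- if (median(post - pre) > 0) "increase" else "decrease"
  }
  structure(
    list(n_events = length(pre), p_value = wt$p.value, direction = dir,
         powers = tibble(onset_s = used_on, pre = pre, post = post),
         band = cfg$burst_band, alpha = alpha, extrema_s = used_T,
         n_clamped = sum(clamped), n_dropped = dropped),
    class = "myo_band_result"
  )
}

#' Full myoelectric session analysis
#'
#' Runs the simple-wave pre/post comparison, locates the per-event
#' modulation extremum in the session's direction, and runs the
#' spike-potential comparison in the mirrored 20 s windows. The
#' spike-potential analysis is always computed; whether to report it only
#' for sessions with a significant simple-wave change is left to the caller
#' (`glance()` exposes both p-values).
#'
#' @param rec A gut [cont_rec()].
#' @param events An [event_series()].
#' @param cfg A [myo_windows()].
#' @param hyp,state Optional hypnogram and state filter.
#' @param NW,K,alpha As elsewhere.
#' @return An object of class `myo_session_result` with elements
#'   `simple_wave`, `spike_potential`, `extrema_s`, `n_events`.
#' @export
myo_session <- function(rec, events, cfg = myo_windows(), hyp = NULL,
                        state = NULL, NW = 3, K = 5L, alpha = 0.05) {
  sw <- simple_wave_response(rec, events, cfg, hyp, state, NW, K, alpha)
  dir <- if (sw$direction == "decrease") "decrease" else "increase"
  used <- sw$powers$onset_s
  sub_events <- event_series(used)
  extrema <- vapply(used, function(on)
    as.numeric(modulation_extremum(rec, on, cfg, dir)), numeric(1))
  sp <- spike_potential_response(rec, sub_events, extrema, cfg, NW, K, alpha)
  structure(
    list(simple_wave = sw, spike_potential = sp, extrema_s = extrema,
         n_events = sw$n_events),
    class = "myo_session_result"
  )
}

#' @export
print.myo_session_result <- function(x, ...) {
  cat(sprintf("<myo_session_result> %d events\n  simple waves: p = %.4g (%s)\n  spike potentials: p = %.4g (%s)\n",
              x$n_events, x$simple_wave$p_value, x$simple_wave$direction,
              x$spike_potential$p_value, x$spike_potential$direction))
  invisible(x)
}

#' @export
glance.myo_session_result <- function(x, ...) {
  tibble(n_events = x$n_events,
         simple_wave_p = x$simple_wave$p_value,
         simple_wave_direction = x$simple_wave$direction,
         spike_potential_p = x$spike_potential$p_value,
         spike_potential_direction = x$spike_potential$direction,
         median_extremum_s = median(x$extrema_s))
}

#' @export
tidy.myo_session_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$simple_wave), component = "simple_wave",
                  .before = 1),
    dplyr::mutate(tidy(x$spike_potential), component = "spike_potential",
                  .before = 1))
}
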