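#' Continuous electrophysiological recording
#'
#' A uniformly sampled signal together with its sampling rate, start time and
#' channel role. This is the common container for cortical local field
#' potentials (LFP), scalp/epidural EEG and gut (duodenal) myoelectric traces.
#' Sample `k` (1-based) is located at `start_time + (k - 1) / rate` seconds.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units; microvolts
#'   for typical real data). Must be finite.
#' @param rate Sampling frequency in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @param channel Role tag, one of `"LFP"`, `"EEG"`, `"GUT"`, `"OTHER"`.
#' @param label Free-text label.
#' @return An object of class `cont_rec`.
#' @examples
#' rec <- cont_rec(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), rate = 500)
#' rec
#' @export
cont_rec <- function(samples, rate, start_time = 0, channel = "OTHER",
                     label = "") {
  if (!is_number(rate) || rate <= 0) {
    stop_evoked("evoked_invalid", "`rate` must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_evoked("evoked_invalid", "`samples` must be finite")
  }
  channel <- match.arg(channel, c("LFP", "EEG", "GUT", "OTHER"))
  structure(
    list(samples = samples, rate = rate, start_time = start_time,
         channel = channel, label = label),
    class = "cont_rec"
  )
}

#' @export
print.cont_rec <- function(x, ...) {
  cat(sprintf("<cont_rec> %s channel%s: %d samples @ %g Hz, t = [%g, %g) s\n",
              x$channel, if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$samples), x$rate, x$start_time,
              x$start_time + length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.cont_rec <- function(x) length(x$samples)

#' Time axis of a recording
#' @param rec A [cont_rec()].
#' @return Numeric vector of sample times in seconds.
#' @export
rec_times <- function(rec) {
  rec$start_time + (seq_along(rec$samples) - 1) / rec$rate
}

#' End time of a recording (half-open convention)
#' @param rec A [cont_rec()].
#' @return `start_time + n / rate`.
#' @export
rec_end <- function(rec) rec$start_time + length(rec$samples) / rec$rate

#' Convert a recording to a tibble
#' @param x A [cont_rec()].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `value`.
#' @export
as_tibble.cont_rec <- function(x, ...) {
  tibble(time_s = rec_times(x), value = x$samples)
}

#' Stimulus event series
#'
#' Stimulus onset times with a per-event artifact flag. Onsets must be
#' strictly increasing.
#'
#' @param onsets Strictly increasing onset times in seconds.
#' @param artifact Logical vector (recycled) flagging events that coincided
#'   with motion artifacts; flagged events are excluded from analysis.
#' @param label Stimulus type tag.
#' @return A tibble of class `event_series` with columns `onset_s`,
#'   `artifact`, `label`.
#' @examples
#' event_series(c(10, 70, 130))
#' @export
event_series <- function(onsets, artifact = FALSE, label = "stim") {
  onsets <- as.numeric(onsets)
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    stop_evoked("evoked_invalid", "event onsets must be strictly increasing")
  }
  out <- tibble(onset_s = onsets,
                artifact = rep_len(as.logical(artifact), length(onsets)),
                label = rep_len(as.character(label), length(onsets)))
  class(out) <- c("event_series", class(out))
  out
}

#' Vigilance-state hypnogram
#'
#' An ordered, non-overlapping set of scored WAKE/SWS intervals. Intervals
#' are half-open `[start_s, end_s)`.
#'
#' @param start_s,end_s Interval bounds in seconds (`end_s > start_s`).
#' @param state Character vector of states, each `"WAKE"` or `"SWS"`.
#' @return A tibble of class `hypnogram` with columns `start_s`, `end_s`,
#'   `state`.
#' @examples
#' hypnogram(c(0, 600), c(600, 1200), c("WAKE", "SWS"))
#' @export
hypnogram <- function(start_s, end_s, state) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  state <- as.character(state)
  if (!all(state %in% c("WAKE", "SWS"))) {
    stop_evoked("evoked_invalid", "states must be 'WAKE' or 'SWS'")
  }
  if (any(end_s <= start_s)) {
    stop_evoked("evoked_invalid", "hypnogram intervals must have end > start")
  }
  if (length(start_s) > 1L) {
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]; state <- state[o]
    if (any(start_s[-1] < end_s[-length(end_s)])) {
      stop_evoked("evoked_invalid", "hypnogram intervals must not overlap")
    }
  }
  out <- tibble(start_s = start_s, end_s = end_s, state = state)
  class(out) <- c("hypnogram", class(out))
  out
}

# State of the single interval that fully contains [t0, t1]; NA_character_
# when the span is unstaged, "state_change" sentinel when it straddles.
span_state <- function(hyp, t0, t1) {
  inside <- hyp$start_s <= t0 & t1 <= hyp$end_s
  if (any(inside)) return(hyp$state[which(inside)[1]])
  overlaps <- hyp$start_s < t1 & t0 < hyp$end_s
  if (any(overlaps)) return("state_change")
  NA_character_
}

#' Sorted spike event times for one unit
#'
#' @param times Strictly increasing spike times in seconds.
#' @param unit_id Unit identifier.
#' @return A tibble of class `spike_train` with columns `unit_id`, `time_s`.
#' @examples
#' spike_train(c(0.1, 0.5, 2.2), unit_id = "u1")
#' @export
spike_train <- function(times, unit_id = "unit") {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_evoked("evoked_invalid", "spike times must be strictly increasing")
  }
  out <- tibble(unit_id = as.character(unit_id), time_s = times)
  class(out) <- c("spike_train", class(out))
  out
}
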