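#' Zero-phase band-pass filter
#'
#' Butterworth filtering applied forward and backward (via
#' [signal::filtfilt()]) so that no group delay is introduced. A band with
#' `lo = 0` is a pure low-pass. Band-pass filtering is realized as a cascade
#' of a 4th-order high-pass and a 4th-order low-pass section, which stays
#' numerically stable even for edges far below the Nyquist frequency (e.g.,
#' 0.3 Hz on a 10 kHz recording).
#'
#' @param rec A [cont_rec()].
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= rate / 2`.
#' @param order Butterworth order per section (default 4).
#' @return A [cont_rec()] with identical rate and length.
#' @examples
#' rec <- cont_rec(rnorm(2000), rate = 200, channel = "EEG")
#' delta <- bandpass(rec, 1, 4)
#' @export
bandpass <- function(rec, lo, hi, order = 4L) {
  stopifnot(inherits(rec, "cont_rec"))
  nyq <- rec$rate / 2
  if (!is_number(lo) || !is_number(hi) || lo < 0 || hi <= lo) {
    stop_evoked("evoked_invalid_band", "need 0 <= lo < hi")
  }
  if (hi > nyq) {
    stop_evoked("evoked_invalid_band",
                sprintf("upper edge %g Hz above Nyquist %g Hz", hi, nyq))
  }
  # filtfilt needs a few filter lengths of warm-up on each side
  if (length(rec$samples) < 6L * (order + 1L)) {
    stop_evoked("evoked_too_short", "recording shorter than filter warm-up")
  }
  x <- rec$samples
  if (lo > 0) {
    bh <- signal::butter(order, lo / nyq, type = "high")
    x <- filtfilt_padded(bh, x, npad_for(rec$rate, lo, length(x)))
  }
  if (hi < nyq) {
    bl <- signal::butter(order, hi / nyq, type = "low")
    x <- filtfilt_padded(bl, x, npad_for(rec$rate, hi, length(x)))
  }
  out <- rec
  out$samples <- as.numeric(x)
  out
}

# Padding length: a few time constants of the band edge, capped by length.
npad_for <- function(rate, edge_hz, n) {
  min(n - 1L, as.integer(ceiling(3 * rate / edge_hz)))
}

# filtfilt with odd-reflection end padding so start-up transients decay in
# the padding, not the signal (the scipy/MATLAB convention; signal::filtfilt
# itself applies none).
filtfilt_padded <- function(filt, x, npad) {
  n <- length(x)
  if (npad < 1L) return(signal::filtfilt(filt, x))
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(npad + 1L):(npad + n)]
}

# Band-limited amplitude envelope: magnitude of the analytic signal of the
# band-passed trace, optionally smoothed with a moving average (seconds).
band_envelope <- function(rec, lo, hi, smooth_s = 0) {
  filt <- bandpass(rec, lo, hi)
  env <- Mod(analytic_signal(filt$samples))
  if (smooth_s > 0) env <- moving_average(env, round(smooth_s * rec$rate))
  out <- rec
  out$samples <- env
  out
}
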