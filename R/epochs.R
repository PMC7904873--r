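#' Trials-by-time epoch matrix
#'
#' Stimulus-locked matrix of signal segments. Row `i` holds the samples of
#' trial `i`; `rel_time` is the half-open time axis `[-pre_s, post_s)`
#' relative to stimulus onset (onset itself belongs to the post-stimulus
#' side). Constructed by [extract_epochs()]; not usually built by hand.
#'
#' @param data Trials x samples numeric matrix.
#' @param rel_time Relative time axis in seconds, uniformly spaced at
#'   `1 / rate`.
#' @param rate Sampling rate in Hz.
#' @param trial_state Optional state label per trial (`"WAKE"`/`"SWS"`).
#' @param trial_ids Provenance indices into the originating event series.
#' @return An object of class `epoch_matrix`.
#' @export
epoch_matrix <- function(data, rel_time, rate, trial_state = NULL,
                         trial_ids = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != length(rel_time)) {
    stop_evoked("evoked_invalid", "ncol(data) must match length(rel_time)")
  }
  if (length(rel_time) > 1L) {
    dt <- diff(rel_time)
    if (max(abs(dt - 1 / rate)) > 1e-9) {
      stop_evoked("evoked_invalid", "rel_time must be uniform at 1/rate")
    }
  }
  if (!is.null(trial_state) && length(trial_state) != nrow(data)) {
    stop_evoked("evoked_invalid", "one state label per trial required")
  }
  structure(
    list(data = data, rel_time = rel_time, rate = rate,
         trial_state = trial_state,
         trial_ids = trial_ids %||% seq_len(nrow(data))),
    class = "epoch_matrix"
  )
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %d trials x %d samples @ %g Hz, rel t [%g, %g) s\n",
              nrow(x$data), ncol(x$data), x$rate, x$rel_time[1],
              x$rel_time[length(x$rel_time)] + 1 / x$rate))
  if (!is.null(x$trial_state)) {
    cat("  states:", paste(sprintf("%s=%d", names(table(x$trial_state)),
                                   table(x$trial_state)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_matrix <- function(x) dim(x$data)

#' Number of trials in an epoch matrix
#' @param epochs An [epoch_matrix()].
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) nrow(epochs$data)

#' Extract stimulus-locked epochs from a continuous recording
#'
#' Cuts a window `[-pre_s, +post_s)` around every stimulus onset. Events
#' whose window would leave the recording are dropped and reported in the
#' `dropped` attribute. Rows are in event order; no resampling is performed,
#' so concatenating epochs reproduces the raw samples bit-exactly.
#'
#' @param rec A [cont_rec()].
#' @param events An [event_series()].
#' @param window Numeric `c(pre_s, post_s)`, both positive: seconds before
#'   and after onset.
#' @return An [epoch_matrix()]; attribute `dropped` is a tibble of dropped
#'   events (columns `trial`, `onset_s`, `reason`).
#' @examples
#' rec <- cont_rec(rnorm(5000), rate = 1000)
#' ep <- extract_epochs(rec, event_series(c(1, 2.5, 4)), c(0.5, 0.5))
#' dim(ep)
#' @export
extract_epochs <- function(rec, events, window) {
  stopifnot(inherits(rec, "cont_rec"))
  pre_s <- window[1]; post_s <- window[2]
  if (pre_s + post_s <= 0 || pre_s < 0 || post_s < 0) {
    stop_evoked("evoked_invalid_window", "window length must be positive")
  }
  pre_n <- as.integer(round(pre_s * rec$rate))
  post_n <- as.integer(round(post_s * rec$rate))
  rel_time <- seq.int(-pre_n, post_n - 1L) / rec$rate
  n <- length(rec$samples)
  if (nrow(events) == 0L) {
    return(epoch_matrix(matrix(numeric(0), 0L, pre_n + post_n), rel_time,
                        rec$rate, trial_state = character(0),
                        trial_ids = integer(0)))
  }
  i0 <- time_to_index(events$onset_s, rec$start_time, rec$rate)
  lo <- i0 - pre_n
  hi <- i0 + post_n - 1L
  ok <- lo >= 1L & hi <= n
  dropped <- tibble(trial = which(!ok), onset_s = events$onset_s[!ok],
                    reason = "window_outside_recording")
  idx <- which(ok)
  dat <- matrix(0, length(idx), pre_n + post_n)
  for (j in seq_along(idx)) {
    dat[j, ] <- rec$samples[lo[idx[j]]:hi[idx[j]]]
  }
  out <- epoch_matrix(dat, rel_time, rec$rate, trial_ids = idx)
  attr(out, "dropped") <- dropped
  attr(out, "window") <- c(pre_s = pre_s, post_s = post_s)
  out
}

#' Exclude trials by vigilance state and artifact flags
#'
#' Retains only trials whose full `[onset - pre_s, onset + post_s]` span lies
#' inside a single hypnogram interval and whose artifact flag is unset, and
#' labels each retained trial with the state of that interval. Trials that
#' coincide with motion artifacts are excluded with reason `"artifact"`;
#' trials whose span straddles a state boundary with reason `"state_change"`;
#' trials outside every scored interval with reason `"unstaged"`.
#'
#' @param epochs An [epoch_matrix()] from [extract_epochs()].
#' @param hyp A [hypnogram()].
#' @param events The same [event_series()] the epochs were cut from.
#' @return The retained [epoch_matrix()] with `trial_state` set; attribute
#'   `exclusions` is a tibble (`trial`, `onset_s`, `reason`).
#' @export
exclude_trials <- function(epochs, hyp, events) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  win <- attr(epochs, "window")
  if (is.null(win)) {
    win <- c(pre_s = -epochs$rel_time[1],
             post_s = epochs$rel_time[length(epochs$rel_time)] + 1 / epochs$rate)
  }
  ids <- epochs$trial_ids
  if (max(ids, 0L) > nrow(events)) {
    stop_evoked("evoked_invalid", "epochs do not match the supplied events")
  }
  onset <- events$onset_s[ids]
  art <- events$artifact[ids]
  state <- character(length(ids))
  reason <- rep(NA_character_, length(ids))
  for (j in seq_along(ids)) {
    if (isTRUE(art[j])) { reason[j] <- "artifact"; next }
    st <- span_state(hyp, onset[j] - win[["pre_s"]], onset[j] + win[["post_s"]])
    if (is.na(st)) reason[j] <- "unstaged"
    else if (st == "state_change") reason[j] <- "state_change"
    else state[j] <- st
  }
  keep <- is.na(reason)
  out <- epoch_matrix(epochs$data[keep, , drop = FALSE], epochs$rel_time,
                      epochs$rate, trial_state = state[keep],
                      trial_ids = ids[keep])
  attr(out, "window") <- win
  attr(out, "exclusions") <- tibble(trial = ids[!keep], onset_s = onset[!keep],
                                    reason = reason[!keep])
  out
}

#' Per-trial z-scoring to the pre-stimulus baseline
#'
#' Transforms each trial to `(x - mean) / sd` using that trial's own
#' statistics over the baseline window (default the 500 ms before onset).
#'
#' @param epochs An [epoch_matrix()].
#' @param baseline Numeric `c(t0, t1)` in relative seconds; half-open
#'   `[t0, t1)` on the sample grid.
#' @return A z-scored [epoch_matrix()].
#' @export
zscore_to_baseline <- function(epochs, baseline = c(-0.5, 0)) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  sel <- epochs$rel_time >= baseline[1] & epochs$rel_time < baseline[2]
  if (sum(sel) < 2L) {
    stop_evoked("evoked_invalid_window", "baseline window not inside rel_time")
  }
  base <- epochs$data[, sel, drop = FALSE]
  mu <- rowMeans(base)
  sdv <- apply(base, 1L, sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    stop_evoked("evoked_degenerate",
                sprintf("zero baseline SD in trial(s) %s",
                        paste(epochs$trial_ids[bad], collapse = ", ")))
  }
  out <- epochs
  out$data <- (epochs$data - mu) / sdv
  out
}

#' Remove a least-squares linear trend from every trial
#'
#' Restricts the epochs to `window` and removes each trial's own best-fit
#' straight line, leaving per-trial zero mean and zero linear trend. This is
#' the detrending step required before the residual orthogonality test.
#'
#' @param epochs An [epoch_matrix()].
#' @param window Numeric `c(t0, t1)` relative seconds, half-open.
#' @return A detrended, windowed [epoch_matrix()].
#' @export
detrend_trials <- function(epochs, window = c(0.040, 0.540)) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  sel <- epochs$rel_time >= window[1] & epochs$rel_time < window[2]
  if (sum(sel) < 3L) {
    stop_evoked("evoked_invalid_window", "detrend window shorter than 3 samples")
  }
  X <- epochs$data[, sel, drop = FALSE]
  t <- epochs$rel_time[sel]
  tc <- t - mean(t)
  # per-row OLS line: slope = X %*% tc / sum(tc^2), intercept = rowMeans
  denom <- sum(tc^2)
  slope <- as.numeric(X %*% tc) / denom
  fitted <- outer(rowMeans(X), rep(1, length(tc))) + outer(slope, tc)
  epoch_matrix(X - fitted, t, epochs$rate, trial_state = epochs$trial_state,
               trial_ids = epochs$trial_ids)
}

#' Trial-averaged waveform of an epoch matrix
#' @param epochs An [epoch_matrix()].
#' @return A tibble with `rel_time`, `mean`, `sem`, `n`.
#' @export
epoch_average <- function(epochs) {
  n <- nrow(epochs$data)
  tibble(rel_time = epochs$rel_time,
         mean = colMeans(epochs$data),
         sem = apply(epochs$data, 2L, sd) / sqrt(max(n, 1L)),
         n = n)
}

# Subset trials of an epoch matrix by state.
epochs_by_state <- function(epochs, state) {
  keep <- !is.na(epochs$trial_state) & epochs$trial_state == state
  out <- epoch_matrix(epochs$data[keep, , drop = FALSE], epochs$rel_time,
                      epochs$rate, trial_state = epochs$trial_state[keep],
                      trial_ids = epochs$trial_ids[keep])
  attr(out, "window") <- attr(epochs, "window")
  out
}
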