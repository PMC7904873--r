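#' Specification of one stimulus-evoked response
#'
#' Parameterizes a state-dependent evoked component used by the LFP and
#' spike-train generators: a causal alpha-function kernel
#' `(t/tau) exp(1 - t/tau)` (with `tau = duration_s / 5`) starting at
#' `latency_s`, or a biphasic positive-then-negative kernel for `sign =
#' "dual"`. For LFP generation `amplitude` is the kernel peak in units of the
#' background-noise SD; for spike generation it is the peak fractional
#' modulation of the baseline rate (1 = 100 %).
#'
#' @param latency_s Onset delay after stimulus, seconds; must be at least
#'   0.04 s (the post-artifact analysis start).
#' @param amplitude Peak response amplitude (see above).
#' @param duration_s Response width in seconds.
#' @param sign `"excitatory"`, `"inhibitory"` or `"dual"`.
#' @param state Vigilance state that expresses the response (`"SWS"` or
#'   `"WAKE"`).
#' @return A tibble row of class `evoked_spec`.
#' @examples
#' evoked_spec(latency_s = 0.1, amplitude = 5, duration_s = 0.2)
#' @export
evoked_spec <- function(latency_s = 0.1, amplitude = 5, duration_s = 0.2,
                        sign = c("excitatory", "inhibitory", "dual"),
                        state = c("SWS", "WAKE")) {
  sign <- match.arg(sign)
  state <- match.arg(state)
  if (latency_s < 0.04) {
    stop_evoked("evoked_invalid", "latency_s must be >= 0.04 s (post-blanking)")
  }
  if (duration_s <= 0) stop_evoked("evoked_invalid", "duration_s must be > 0")
  out <- tibble(latency_s = latency_s, amplitude = amplitude,
                duration_s = duration_s, sign = sign, state = state)
  class(out) <- c("evoked_spec", class(out))
  out
}

#' Evaluate a response kernel
#'
#' The stereotyped evoked-response shape used by the generators: a causal
#' alpha function `(s/tau) exp(1 - s/tau)` with `tau = duration_s / 5` and
#' `s = t - latency_s`, peak value 1 at `latency_s + tau`; negated for
#' inhibitory responses and positive-then-negative for dual ones.
#'
#' @param t Times relative to stimulus onset (s).
#' @param latency_s Response onset (s).
#' @param duration_s Response width (s).
#' @param sign `"excitatory"`, `"inhibitory"` or `"dual"`.
#' @return Kernel values at `t`.
#' @export
response_kernel <- function(t, latency_s, duration_s, sign = "excitatory") {
  tau <- duration_s / 5
  up <- function(tt) {
    s <- pmax(tt, 0) / tau
    ifelse(tt > 0, s * exp(1 - s), 0)
  }
  if (sign == "dual") {
    up(t - latency_s) - up(t - latency_s - duration_s / 2)
  } else if (sign == "inhibitory") {
    -up(t - latency_s)
  } else {
    up(t - latency_s)
  }
}

#' Specification of the duodenal myoelectric generator
#'
#' @param slow_wave_hz Fundamental of the simple waves (electrical control
#'   activity); must be below 2 Hz. Default 0.3 Hz.
#' @param burst_rate_per_min Expected spike-potential packets per minute
#'   (postprandial contractions occur at roughly 4-5 per minute).
#' @param burst_band_hz Band of the burst packets, default `c(3, 10)` Hz.
#' @param stim_gain Multiplicative change of slow-wave amplitude after each
#'   stimulus delivered in `stim_state` (1 = no effect).
#' @param stim_effect_s Duration of the post-stimulus amplitude change.
#' @param burst_stim_gain Multiplicative change of the burst-packet rate in
#'   the same post-stimulus window (1 = no effect).
#' @param stim_state State in which stimulation is effective (default SWS).
#' @return A list of class `gut_spec`.
#' @export
gut_spec <- function(slow_wave_hz = 0.3, burst_rate_per_min = 4.5,
                     burst_band_hz = c(3, 10), stim_gain = 1,
                     stim_effect_s = 40, burst_stim_gain = 1,
                     stim_state = "SWS") {
  if (slow_wave_hz >= 2) {
    stop_evoked("evoked_invalid", "slow_wave_hz must be below 2 Hz")
  }
  if (burst_band_hz[1] <= 2 || burst_band_hz[2] <= burst_band_hz[1]) {
    stop_evoked("evoked_invalid", "burst band must lie inside (2, rate/2)")
  }
  structure(
    list(slow_wave_hz = slow_wave_hz, burst_rate_per_min = burst_rate_per_min,
         burst_band_hz = burst_band_hz, stim_gain = stim_gain,
         stim_effect_s = stim_effect_s, burst_stim_gain = burst_stim_gain,
         stim_state = stim_state),
    class = "gut_spec"
  )
}

#' Build a hypnogram from consecutive state segments
#'
#' @param states Character vector of states (`"WAKE"`/`"SWS"`).
#' @param durations_s Positive segment durations in seconds.
#' @return A [hypnogram()] of contiguous intervals starting at 0.
#' @examples
#' gen_hypnogram(c("WAKE", "SWS"), c(600, 600))
#' @export
gen_hypnogram <- function(states, durations_s) {
  if (length(states) != length(durations_s)) {
    stop_evoked("evoked_invalid", "states and durations_s must match")
  }
  if (length(states) == 0L) {
    return(hypnogram(numeric(0), numeric(0), character(0)))
  }
  if (any(durations_s <= 0)) {
    stop_evoked("evoked_invalid", "durations must be positive")
  }
  ends <- cumsum(durations_s)
  hypnogram(c(0, head(ends, -1L)), ends, states)
}

#' Generate stimulus onset times with uniform interstimulus intervals
#'
#' Onsets are drawn with i.i.d. uniform ISIs on `[min_s, max_s]` (the
#' intestinal stimulation protocol used 45-60 s) and confined to the
#' hypnogram span.
#'
#' @param hyp A [hypnogram()].
#' @param isi Numeric `c(min_s, max_s)`, both positive.
#' @param seed Optional integer seed for reproducibility.
#' @return An [event_series()].
#' @export
gen_stim_times <- function(hyp, isi = c(45, 60), seed = NULL) {
  if (isi[1] > isi[2] || isi[1] <= 0) {
    stop_evoked("evoked_invalid", "need 0 < min_s <= max_s")
  }
  if (nrow(hyp) == 0L) return(event_series(numeric(0)))
  t0 <- min(hyp$start_s); t1 <- max(hyp$end_s)
  if (t1 - t0 < isi[1]) {
    rlang::warn("hypnogram span shorter than the minimum ISI; no events")
    return(event_series(numeric(0)))
  }
  with_seed(seed, {
    onsets <- numeric(0)
    t <- t0 + runif(1, isi[1], isi[2])
    while (t < t1) {
      onsets <- c(onsets, t)
      t <- t + runif(1, isi[1], isi[2])
    }
    event_series(onsets)
  })
}

# Per-sample state labels for a time grid, stepping at hypnogram boundaries.
state_at <- function(hyp, times) {
  if (nrow(hyp) == 0L) return(rep(NA_character_, length(times)))
  idx <- findInterval(times, hyp$start_s)
  st <- c(NA_character_, hyp$state)[idx + 1L]
  st[idx >= 1L & times >= hyp$end_s[pmax(idx, 1L)]] <- NA_character_
  st
}

# Unit-variance band-limited Gaussian noise of length n.
band_noise <- function(n, rate, lo, hi) {
  x <- bandpass(cont_rec(rnorm(n), rate), lo, hi)$samples
  x / sd(x)
}

#' Generate EEG with state-dependent band power
#'
#' The signal is a sum over bands of `gain(state, band)` times band-limited
#' unit-variance Gaussian noise; gains switch at hypnogram boundaries, so
#' band power scales with the squared gain within each state. Emulates EEG
#' whose delta and spindle power rise in slow wave sleep while gamma power
#' falls.
#'
#' @param hyp A [hypnogram()] (the recording spans it).
#' @param gains Named list with one numeric vector per state, each with one
#'   gain per band of `bands` (e.g. `list(WAKE = c(delta = 1, spindles = 1,
#'   gamma = 1), SWS = c(delta = 2, spindles = 2, gamma = 0.5))`).
#' @param bands A [band_set()].
#' @param rate Sampling rate in Hz (>= 200 so the 75 Hz gamma edge exists).
#' @param seed Optional seed.
#' @return A [cont_rec()] with channel `"EEG"`.
#' @export
gen_eeg <- function(hyp,
                    gains = list(WAKE = c(delta = 1, spindles = 1, gamma = 1),
                                 SWS = c(delta = 2, spindles = 2, gamma = 0.5)),
                    bands = band_set(), rate = 200, seed = NULL) {
  if (rate < 200) stop_evoked("evoked_invalid", "rate must be >= 200 Hz")
  if (any(bands$hi_hz > rate / 2)) {
    stop_evoked("evoked_invalid_band", "band above Nyquist")
  }
  if (any(unlist(gains) < 0)) stop_evoked("evoked_invalid", "gains must be >= 0")
  t1 <- max(hyp$end_s)
  n <- as.integer(round(t1 * rate))
  times <- (0:(n - 1L)) / rate
  st <- state_at(hyp, times)
  st[is.na(st)] <- hyp$state[nrow(hyp)]
  with_seed(seed, {
    sig <- numeric(n)
    for (i in seq_len(nrow(bands))) {
      g <- numeric(n)
      for (s in unique(st)) g[st == s] <- gains[[s]][[bands$band[i]]]
      if (all(g == 0)) next
      sig <- sig + g * band_noise(n, rate, bands$lo_hz[i], bands$hi_hz[i])
    }
    cont_rec(sig, rate, channel = "EEG", label = "synthetic EEG")
  })
}

# 1/f^beta Gaussian noise via spectral synthesis, standardized to `sd`.
colored_noise <- function(n, rate, beta = 1, sd_target = 1) {
  nfft <- stats::nextn(n, 2L)
  f <- c(0, seq_len(nfft - 1L)) * rate / nfft
  f[(nfft %/% 2L + 2L):nfft] <- f[seq.int(nfft %/% 2L, 2L)]  # mirror
  amp <- c(0, f[-1L]^(-beta / 2))
  half <- nfft %/% 2L
  z <- complex(real = rnorm(nfft), imaginary = rnorm(nfft))
  spec <- amp * z
  x <- Re(stats::fft(spec, inverse = TRUE)) / nfft
  x <- x[1:n]
  x * sd_target / sd(x)
}

#' Generate an LFP recording with state-dependent evoked responses
#'
#' Colored (1/f^beta) Gaussian background plus, for every stimulus delivered
#' in a spec's state, that spec's response kernel ([evoked_spec()]).
#'
#' @param hyp A [hypnogram()].
#' @param events An [event_series()].
#' @param specs An [evoked_spec()] tibble (zero or more rows).
#' @param noise Named numeric `c(exponent = , sd = )`: spectral exponent
#'   beta of the 1/f^beta background and its SD.
#' @param rate Sampling rate in Hz.
#' @param seed Optional seed.
#' @return A [cont_rec()] with channel `"LFP"`.
#' @export
gen_lfp_evoked <- function(hyp, events, specs = evoked_spec(),
                           noise = c(exponent = 1, sd = 1), rate = 1000,
                           seed = NULL) {
  if (nrow(specs) > 0 && !all(specs$state %in% c("WAKE", "SWS"))) {
    stop_evoked("evoked_invalid", "spec states must be WAKE or SWS")
  }
  t1 <- max(hyp$end_s)
  n <- as.integer(round(t1 * rate))
  with_seed(seed, {
    sig <- colored_noise(n, rate, beta = noise[["exponent"]],
                         sd_target = noise[["sd"]])
    if (nrow(events) > 0L && nrow(specs) > 0L) {
      ev_state <- state_at(hyp, events$onset_s)
      for (i in seq_len(nrow(specs))) {
        sp <- specs[i, ]
        hit <- which(!is.na(ev_state) & ev_state == sp$state)
        if (!length(hit)) next
        span <- sp$latency_s + 2 * sp$duration_s
        m <- as.integer(ceiling(span * rate))
        tk <- (0:(m - 1L)) / rate
        kern <- sp$amplitude * noise[["sd"]] *
          response_kernel(tk, sp$latency_s, sp$duration_s, sp$sign)
        for (on in events$onset_s[hit]) {
          j0 <- time_to_index(on, 0, rate)
          j1 <- min(j0 + m - 1L, n)
          if (j0 <= n) sig[j0:j1] <- sig[j0:j1] + kern[1:(j1 - j0 + 1L)]
        }
      }
    }
    cont_rec(sig, rate, channel = "LFP", label = "synthetic LFP")
  })
}

#' Generate an inhomogeneous-Poisson spike train
#'
#' Spikes are drawn by thinning a homogeneous Poisson process whose rate is
#' the state-dependent baseline times the event-locked modulation given by
#' the specs: excitatory specs scale the rate by `1 + amplitude * kernel`,
#' inhibitory specs by `max(0, 1 - amplitude * kernel)`, dual specs by the
#' biphasic kernel (clipped at zero with a warning if driven negative).
#'
#' @param hyp A [hypnogram()].
#' @param events An [event_series()].
#' @param baseline_hz Named numeric baseline rate per state
#'   (`c(WAKE = , SWS = )`), or a single rate for both; must be positive.
#' @param specs An [evoked_spec()] tibble (amplitude = peak fractional rate
#'   modulation).
#' @param seed Optional seed.
#' @param unit_id Unit label.
#' @return A [spike_train()].
#' @export
gen_spikes <- function(hyp, events, baseline_hz = 10,
                       specs = evoked_spec()[0, ], seed = NULL,
                       unit_id = "unit") {
  if (length(baseline_hz) == 1L && is.null(names(baseline_hz))) {
    baseline_hz <- c(WAKE = unname(baseline_hz), SWS = unname(baseline_hz))
  }
  if (any(baseline_hz <= 0)) {
    stop_evoked("evoked_invalid", "baseline_hz must be positive")
  }
  t1 <- max(hyp$end_s)
  amp_max <- if (nrow(specs)) max(1 + abs(specs$amplitude)) else 1
  lam_max <- max(baseline_hz) * amp_max
  rate_at <- function(tt) {
    st <- state_at(hyp, tt)
    base <- ifelse(is.na(st), 0, baseline_hz[st])
    mod <- rep(1, length(tt))
    if (nrow(specs) > 0L && nrow(events) > 0L) {
      prev <- findInterval(tt, events$onset_s)
      has <- prev >= 1L
      rel <- tt - events$onset_s[pmax(prev, 1L)]
      ev_state <- state_at(hyp, events$onset_s[pmax(prev, 1L)])
      for (i in seq_len(nrow(specs))) {
        sp <- specs[i, ]
        act <- has & !is.na(ev_state) & ev_state == sp$state & !is.na(st) &
          st == sp$state & rel >= sp$latency_s &
          rel <= sp$latency_s + 2 * sp$duration_s
        if (!any(act)) next
        k <- response_kernel(rel[act], sp$latency_s, sp$duration_s, sp$sign)
        mod[act] <- mod[act] * (1 + sp$amplitude * k)
      }
    }
    neg <- mod < 0
    if (any(neg)) {
      rlang::warn("modulation drove the rate negative; clipped at 0")
      mod[neg] <- 0
    }
    base * mod
  }
  with_seed(seed, {
    n_cand <- rpois(1, lam_max * t1)
    # a Poisson process has a.s. distinct points; drop the rare duplicates
    # produced by the RNG's finite granularity
    cand <- unique(sort(runif(n_cand, 0, t1)))
    keep <- runif(length(cand)) < rate_at(cand) / lam_max
    spike_train(cand[keep], unit_id = unit_id)
  })
}

#' Generate a duodenal myoelectric recording
#'
#' A slow-wave carrier at `slow_wave_hz` with slowly varying lognormal
#' amplitude, Poisson-placed 3-10 Hz burst packets snapped to slow-wave
#' crests, and low-level white measurement noise. If `stim_gain != 1`, the
#' slow-wave amplitude is multiplied by `stim_gain` for `stim_effect_s`
#' seconds (starting 0.5 s after onset) after each stimulus delivered in
#' `stim_state`; `burst_stim_gain` likewise scales the burst-packet rate in
#' that window.
#'
#' @param hyp A [hypnogram()].
#' @param events An [event_series()].
#' @param spec A [gut_spec()].
#' @param rate Sampling rate in Hz (>= 50).
#' @param seed Optional seed.
#' @return A [cont_rec()] with channel `"GUT"`.
#' @export
gen_gut <- function(hyp, events, spec = gut_spec(), rate = 200, seed = NULL) {
  if (rate < 50) stop_evoked("evoked_invalid", "rate must be >= 50 Hz")
  t1 <- max(hyp$end_s)
  n <- as.integer(round(t1 * rate))
  times <- (0:(n - 1L)) / rate
  with_seed(seed, {
    phi <- runif(1, 0, 2 * pi)
    # lognormal amplitude with ~20 s correlation time; smooth a longer noise
    # vector and keep the interior so the ends are not edge-contaminated
    w <- round(20 * rate)
    z <- moving_average(rnorm(n + 2L * w), w)[(w + 1L):(w + n)]
    amp <- exp(0.3 * z * sqrt(w))
    amp <- amp / mean(amp)
    # post-stimulus amplitude window (state-gated)
    gain <- rep(1, n)
    brate <- rep(spec$burst_rate_per_min / 60, n)
    if (nrow(events) > 0L) {
      ev_state <- state_at(hyp, events$onset_s)
      for (j in which(!is.na(ev_state) & ev_state == spec$stim_state)) {
        i0 <- time_to_index(events$onset_s[j] + 0.5, 0, rate)
        i1 <- min(time_to_index(events$onset_s[j] + 0.5 + spec$stim_effect_s,
                                0, rate), n)
        if (i0 <= n) {
          gain[i0:i1] <- gain[i0:i1] * spec$stim_gain
          brate[i0:i1] <- brate[i0:i1] * spec$burst_stim_gain
        }
      }
    }
    slow <- amp * gain * sin(2 * pi * spec$slow_wave_hz * times + phi)
    # burst packets at slow-wave crests
    sig <- slow
    if (spec$burst_rate_per_min > 0) {
      lam_max <- max(brate)
      n_cand <- rpois(1, lam_max * t1)
      cand <- sort(runif(n_cand, 0, t1))
      keep <- runif(n_cand) < brate[pmax(time_to_index(cand, 0, rate), 1L)] /
        lam_max
      cand <- cand[keep]
      if (length(cand)) {
        # snap to the nearest crest of the carrier
        k <- round((2 * pi * spec$slow_wave_hz * cand + phi - pi / 2) /
                     (2 * pi))
        crest <- (pi / 2 - phi + 2 * pi * k) / (2 * pi * spec$slow_wave_hz)
        dur <- 1.5
        m <- as.integer(dur * rate)
        win <- 0.5 * (1 - cos(2 * pi * (0:(m - 1L)) / (m - 1L)))  # Hann
        for (tc in crest) {
          i0 <- time_to_index(tc - dur / 2, 0, rate)
          if (i0 < 1L || i0 + m - 1L > n) next
          packet <- band_noise(m, rate, spec$burst_band_hz[1],
                               spec$burst_band_hz[2]) * win * 0.8
          sig[i0:(i0 + m - 1L)] <- sig[i0:(i0 + m - 1L)] + packet
        }
      }
    }
    sig <- sig + rnorm(n, sd = 0.05)
    cont_rec(sig, rate, channel = "GUT", label = "synthetic duodenum")
  })
}
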