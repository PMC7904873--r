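# Shared fixture builders; everything is generated in code at test time.

# Epoch matrix of i.i.d. standard normal noise on the ROT analysis grid.
noise_epochs <- function(n_trials = 30, n_samples = 500, rate = 1000,
                         t0 = 0.040) {
  epoch_matrix(matrix(rnorm(n_trials * n_samples), n_trials),
               seq(t0, length.out = n_samples, by = 1 / rate), rate)
}

# Add a common waveform (one value per sample) to every trial.
add_common <- function(epochs, waveform) {
  epochs$data <- epochs$data + rep(waveform, each = nrow(epochs$data))
  epochs
}

# Brute-force all-pairs product-sum total (independent oracle for the ROT).
pair_sum_total_bruteforce <- function(X) {
  n <- nrow(X)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) tot <- tot + sum(X[i, ] * X[j, ])
  }
  tot
}

# Closed-form identity for the same total.
pair_sum_total_closed <- function(X) {
  (sum(colSums(X)^2) - sum(X^2)) / 2
}

# Deterministic rate curve: baseline with unit SD (alternating pattern) plus
# an injected deviation `bump` (a function of time, in SD units) in the
# analysis window. Grid matches spike_density (1 ms, window (-0.5, 0.5)).
constructed_curve <- function(bump = function(t) 0, baseline_mean = 20) {
  grid <- seq(-0.5, 0.499, by = 0.001)
  base_pattern <- rep(c(-1, 1), length.out = length(grid))
  rate <- baseline_mean + base_pattern
  sel <- grid >= 0
  rate[sel] <- baseline_mean + vapply(grid[sel], bump, numeric(1))
  bsel <- grid >= -0.5 & grid < 0
  structure(
    list(rel_time = grid, mean = rate,
         trial_rates = matrix(rate, 1), n_trials = 1,
         baseline_mean = mean(rate[bsel]), baseline_sd = sd(rate[bsel]),
         baseline_window = c(-0.5, 0), sigma = 0.02),
    class = "rate_curve"
  )
}

# Homogeneous-Poisson peristimulus design: n_trials disjoint trials at
# `rate_hz`, returned as (train, events) ready for spike_density().
poisson_trials <- function(rate_hz, n_trials, span = 1.2) {
  onsets <- (seq_len(n_trials) - 1) * 2 + 1
  times <- sort(unlist(lapply(onsets, function(o) {
    o + runif(rpois(1, rate_hz * span), -span / 2, span / 2)
  })))
  list(train = spike_train(unique(times)), events = event_series(onsets))
}

# One synthetic gut stimulation session (insular-stimulation protocol:
# ~120 s ISI), all slow wave sleep.
gut_session <- function(stim_gain = 1, burst_stim_gain = 1, n_events = 10,
                        seed = 1, rate = 200) {
  hyp <- gen_hypnogram("SWS", n_events * 120 + 180)
  ev <- gen_stim_times(hyp, c(118, 122), seed = seed)
  gut <- gen_gut(hyp, ev, gut_spec(stim_gain = stim_gain,
                                   burst_stim_gain = burst_stim_gain),
                 rate = rate, seed = seed + 1L)
  list(hyp = hyp, events = ev, rec = gut)
}
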