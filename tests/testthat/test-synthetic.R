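test_that("hypnogram generation produces contiguous ordered intervals", {
  h <- gen_hypnogram(c("WAKE", "SWS"), c(600, 600))
  expect_equal(nrow(h), 2L)
  expect_equal(max(h$end_s), 1200)
  expect_equal(nrow(gen_hypnogram(character(0), numeric(0))), 0L)
  h4 <- gen_hypnogram(rep(c("WAKE", "SWS"), 2), rep(300, 4))
  expect_equal(h4$start_s, c(0, 300, 600, 900))
  expect_error(gen_hypnogram("NAP", 100), class = "evoked_invalid")
})

test_that("stimulus trains have uniform ISIs inside the span and are
          seed-reproducible", {
  hyp <- gen_hypnogram("SWS", 1200)
  a <- gen_stim_times(hyp, c(45, 60), seed = 4)
  b <- gen_stim_times(hyp, c(45, 60), seed = 4)
  expect_identical(a$onset_s, b$onset_s)
  expect_gte(nrow(a), 19L)           # 1200 / 60 minus the leading ISI
  expect_lte(nrow(a), 26L)           # 1200 / 45
  expect_true(all(diff(a$onset_s) >= 45 & diff(a$onset_s) <= 60))
  expect_true(all(a$onset_s > 0 & a$onset_s < 1200))

  per <- gen_stim_times(hyp, c(60, 60), seed = 1)
  expect_equal(diff(per$onset_s), rep(60, nrow(per) - 1L))

  short <- gen_hypnogram("SWS", 30)
  expect_warning(e <- gen_stim_times(short, c(45, 60), seed = 1))
  expect_equal(nrow(e), 0L)
})

test_that("all generators are pure functions of (parameters, seed)", {
  hyp <- gen_hypnogram(c("WAKE", "SWS"), c(120, 120))
  ev <- gen_stim_times(hyp, c(20, 25), seed = 2)
  expect_identical(gen_eeg(hyp, seed = 3)$samples,
                   gen_eeg(hyp, seed = 3)$samples)
  expect_identical(
    gen_lfp_evoked(hyp, ev, evoked_spec(), rate = 500, seed = 3)$samples,
    gen_lfp_evoked(hyp, ev, evoked_spec(), rate = 500, seed = 3)$samples)
  expect_identical(gen_spikes(hyp, ev, 10, seed = 3)$time_s,
                   gen_spikes(hyp, ev, 10, seed = 3)$time_s)
  expect_identical(gen_gut(hyp, ev, seed = 3)$samples,
                   gen_gut(hyp, ev, seed = 3)$samples)
})

test_that("EEG band gains control measured band power", {
  hyp <- gen_hypnogram(c("WAKE", "SWS"), c(200, 200))
  # gain 2 in SWS delta -> power ratio ~ 4; averaged over seeds
  ratios <- vapply(1:4, function(s) {
    eeg <- gen_eeg(hyp, seed = s)
    pw <- function(t0) band_power(
      multitaper_psd(rec_slice(eeg, t0, t0 + 60)), c(1, 4))
    pw(210) / pw(10)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.8)

  # zero gamma gain: only filter leakage remains in the gamma band
  eeg0 <- gen_eeg(hyp, gains = list(WAKE = c(delta = 1, spindles = 1,
                                             gamma = 0),
                                    SWS = c(delta = 1, spindles = 1,
                                            gamma = 0)), seed = 1)
  psd <- multitaper_psd(rec_slice(eeg0, 10, 70))
  expect_lt(band_power(psd, c(30, 75)), 0.01 * band_power(psd, c(1, 4)))

  expect_error(gen_eeg(hyp, rate = 100), class = "evoked_invalid")
  expect_error(gen_eeg(hyp, bands = band_set(gamma = c(30, 120)),
                       rate = 200), class = "evoked_invalid_band")
})

test_that("evoked LFP responses are expressed only in the bound state", {
  hyp <- gen_hypnogram(c("WAKE", "SWS"), c(300, 300))
  ev <- gen_stim_times(hyp, c(10, 12), seed = 5)
  spec <- evoked_spec(latency_s = 0.1, amplitude = 8, duration_s = 0.2,
                      state = "SWS")
  rec <- gen_lfp_evoked(hyp, ev, spec, rate = 500, seed = 5)
  ep <- exclude_trials(extract_epochs(rec, ev, c(0.5, 0.6)), hyp, ev)
  wake_avg <- epoch_average(epochs_by_state(ep, "WAKE"))
  sws_avg <- epoch_average(epochs_by_state(ep, "SWS"))
  post <- wake_avg$rel_time > 0.05 & wake_avg$rel_time < 0.4
  # wake trials carry no response beyond noise; SWS trials carry a large one
  expect_lt(max(abs(wake_avg$mean[post])), 5 * max(wake_avg$sem[post]))
  expect_gt(max(sws_avg$mean[post]), 4)
})

test_that("evoked-spec invariants hold and the dual kernel is biphasic", {
  expect_error(evoked_spec(latency_s = 0.01), class = "evoked_invalid")
  expect_error(evoked_spec(duration_s = 0), class = "evoked_invalid")
  t <- seq(0, 1, by = 1e-3)
  k <- response_kernel(t, 0.1, 0.2, "dual")
  expect_gt(max(k), 0.5)
  expect_lt(min(k), -0.5)
  expect_equal(k[t <= 0.1], rep(0, sum(t <= 0.1)))
})

test_that("Poisson spike generator hits its expected count and rate
          modulation is recoverable", {
  hyp <- gen_hypnogram("SWS", 1000)
  tr <- gen_spikes(hyp, event_series(numeric(0)), baseline_hz = 10,
                   seed = 11)
  expect_lt(abs(nrow(tr) - 10000), 3 * sqrt(10000))

  # excitatory spec produces a bump at the spec latency
  ev <- gen_stim_times(hyp, c(8, 10), seed = 12)
  spec <- evoked_spec(latency_s = 0.15, amplitude = 4, duration_s = 0.15,
                      state = "SWS")
  tr2 <- gen_spikes(hyp, ev, baseline_hz = 15, specs = spec, seed = 12)
  rc <- spike_density(tr2, ev)
  call <- detect_response(rc)
  expect_true(call$significant)
  expect_equal(call$sign, "excitatory")
  expect_lt(abs(call$onset_latency_s - 0.15), 0.05)

  expect_error(gen_spikes(hyp, ev, baseline_hz = 0), class = "evoked_invalid")
})

test_that("a nearly silent unit yields a degenerate, non-significant call
          rather than an error", {
  hyp <- gen_hypnogram("SWS", 500)
  ev <- gen_stim_times(hyp, c(8, 10), seed = 3)
  tr <- gen_spikes(hyp, ev, baseline_hz = 0.001, seed = 3)
  rc <- spike_density(tr, ev)
  call <- detect_response(rc)
  expect_false(call$significant)
})

test_that("gut generator invariants: slow-wave band dominates and bursts
          appear only when requested", {
  hyp <- gen_hypnogram("SWS", 400)
  ev <- event_series(numeric(0))
  no_burst <- gen_gut(hyp, ev, gut_spec(burst_rate_per_min = 0), seed = 6)
  psd <- multitaper_psd(rec_slice(no_burst, 50, 250))
  expect_lt(band_power(psd, c(3, 10)), 0.02 * band_power(psd, c(0, 2)))

  with_burst <- gen_gut(hyp, ev, gut_spec(burst_rate_per_min = 8), seed = 6)
  psd2 <- multitaper_psd(rec_slice(with_burst, 50, 250))
  expect_gt(band_power(psd2, c(3, 10)), 3 * band_power(psd, c(3, 10)))

  expect_error(gut_spec(slow_wave_hz = 2.5), class = "evoked_invalid")
  expect_error(gut_spec(burst_band_hz = c(1, 10)), class = "evoked_invalid")
})
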