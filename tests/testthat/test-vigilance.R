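test_that("Slepian tapers match the reference values and are orthonormal", {
  tp <- dpss_tapers(64, 3, 5)
  # frozen from scipy.signal.windows.dpss(64, 3, 5, return_ratios=True)
  expect_equal(tp$eigen,
               c(0.999999873041, 0.99999115159, 0.999723369226,
                 0.995004912341, 0.946584183646), tolerance = 1e-8)
  expect_equal(abs(tp$tapers[1:4, 1]),
               c(0.00035644421, 0.000791188785, 0.001468275836,
                 0.002459278531), tolerance = 1e-7)
  expect_equal(abs(tp$tapers[1:4, 3]),
               c(0.011839220722, 0.01986776364, 0.029936408469,
                 0.042028945154), tolerance = 1e-7)
  expect_lt(max(abs(crossprod(tp$tapers) - diag(5))), 1e-10)
  expect_error(dpss_tapers(64, 3, 6), class = "evoked_invalid_taper")
})

test_that("the multitaper PSD finds spectral peaks at the right frequency
          and integrates to the variance", {
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  seg <- cont_rec(sin(2 * pi * 10 * t), 200)
  psd <- multitaper_psd(seg)
  f_peak <- psd$freq_hz[which.max(psd$power)]
  expect_lt(abs(f_peak - 10), 3 / 10)       # NW / segment length

  set.seed(61)
  ratios <- replicate(10, {
    x <- rnorm(2000, sd = 2)
    p <- multitaper_psd(cont_rec(x, 200))
    sum((p$power[-1] + p$power[-length(p$power)]) / 2 *
          diff(p$freq_hz)) / var(x)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)

  zero <- multitaper_psd(cont_rec(rep(0, 2000), 200))
  expect_true(all(zero$power == 0))
  expect_error(multitaper_psd(cont_rec(rnorm(2000), 200), NW = 3, K = 7),
               class = "evoked_invalid_taper")
  expect_error(multitaper_psd(cont_rec(rnorm(50), 200)),
               class = "evoked_too_short")
})

test_that("PSD scales as the squared amplitude and ignores constant
          offsets", {
  set.seed(62)
  x <- rnorm(2000)
  p1 <- multitaper_psd(cont_rec(x, 200))
  p3 <- multitaper_psd(cont_rec(3 * x, 200))
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-10)
  poff <- multitaper_psd(cont_rec(x + 100, 200))
  expect_equal(poff$power, p1$power, tolerance = 1e-8)
})

test_that("band power integrates the density with edge interpolation", {
  psd <- structure(
    list(freq_hz = seq(0, 100, by = 0.5), power = rep(2, 201),
         K = 5L, NW = 3, segment_s = 10, rate = 200),
    class = "psd_estimate")
  expect_equal(band_power(psd, c(1, 4)), 6)          # 3 Hz x density 2
  expect_equal(band_power(psd, c(0.25, 4.25)), 8)    # off-grid edges
  psd0 <- psd; psd0$power <- rep(0, 201)
  expect_equal(band_power(psd0, c(1, 4)), 0)
  total <- band_power(psd, c(0, 100))
  expect_lte(band_power(psd, c(1, 4)) + band_power(psd, c(7, 14)) +
               band_power(psd, c(30, 75)), total)
  expect_error(band_power(psd, c(120, 130)), class = "evoked_invalid_band")
})

test_that("state comparison recovers the generator's band-gain ordering
          with strong significance", {
  hyp <- gen_hypnogram(c("WAKE", "SWS"), c(310, 310))
  eeg <- gen_eeg(hyp, seed = 63)
  res <- compare_states(eeg, hyp)
  expect_equal(res$direction,
               c("higher_in_sws", "higher_in_sws", "higher_in_wake"))
  expect_true(all(res$p_value < 0.001))
  expect_true(all(res$n_sws >= 30))

  single <- gen_hypnogram("SWS", 310)
  expect_error(compare_states(eeg, single), class = "evoked_insufficient")
  tiny <- gen_hypnogram(c("WAKE", "SWS"), c(25, 310))
  expect_error(compare_states(eeg, tiny), class = "evoked_insufficient")
})

test_that("stationary EEG is not flagged as awakening while injected
          post-stimulus gamma is", {
  hyp <- gen_hypnogram("SWS", 500)
  ev <- gen_stim_times(hyp, c(22, 25), seed = 64)
  eeg <- gen_eeg(hyp, seed = 64)
  dv <- disturbance_test(eeg, ev, hyp, state = "SWS")
  expect_false(dv$awakening)
  expect_equal(nrow(dv$per_band), 3L)
  expect_gte(dv$n_events_used, 6L)

  # double the gamma amplitude for 10 s after every stimulus
  g <- evokedstate:::band_noise(length(eeg$samples), 200, 30, 75)
  mask <- rep(0, length(eeg$samples))
  for (on in ev$onset_s) {
    i0 <- evokedstate:::time_to_index(on, 0, 200)
    i1 <- min(evokedstate:::time_to_index(on + 10, 0, 200), length(mask))
    mask[i0:i1] <- 1
  }
  eeg2 <- eeg
  eeg2$samples <- eeg$samples + 1.2 * g * mask
  dv2 <- disturbance_test(eeg2, ev, hyp, state = "SWS")
  expect_true(dv2$awakening)
  expect_equal(dv2$per_band$direction[dv2$per_band$band == "gamma"],
               "increase")
  # a gamma rise is cortical activation, not a somnogenic change
  expect_false(dv2$somnogenic_hint)
})

test_that("the disturbance test needs at least six usable events and drops
          boundary-crossing windows", {
  hyp <- gen_hypnogram("SWS", 140)
  eeg <- gen_eeg(hyp, seed = 65)
  ev <- event_series(seq(15, 135, by = 24))  # 6 events, last too close to end
  expect_error(disturbance_test(eeg, ev, hyp, state = "SWS"),
               class = "evoked_insufficient")

  hyp2 <- gen_hypnogram(c("SWS", "WAKE"), c(150, 150))
  eeg2 <- gen_eeg(hyp2, seed = 66)
  # 6 events in SWS but one window crosses the state boundary -> 5 usable
  ev2 <- event_series(c(15, 32, 49, 66, 83, 145))
  expect_error(disturbance_test(eeg2, ev2, hyp2, state = "SWS"),
               class = "evoked_insufficient")
})

test_that("a somnogenic change (delta increase) is hinted, not called an
          awakening", {
  hyp <- gen_hypnogram("SWS", 500)
  ev <- gen_stim_times(hyp, c(22, 25), seed = 67)
  eeg <- gen_eeg(hyp, seed = 67)
  d <- evokedstate:::band_noise(length(eeg$samples), 200, 1, 4)
  mask <- rep(0, length(eeg$samples))
  for (on in ev$onset_s) {
    i0 <- evokedstate:::time_to_index(on, 0, 200)
    i1 <- min(evokedstate:::time_to_index(on + 10, 0, 200), length(mask))
    mask[i0:i1] <- 1
  }
  eeg$samples <- eeg$samples + 2 * d * mask
  dv <- disturbance_test(eeg, ev, hyp, state = "SWS")
  expect_true(dv$somnogenic_hint)
  expect_false(dv$awakening)
})
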