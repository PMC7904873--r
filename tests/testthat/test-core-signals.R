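test_that("domain type constructors enforce their invariants", {
  expect_error(cont_rec(c(1, NA), 100), class = "evoked_invalid")
  expect_error(cont_rec(1:10, -1), class = "evoked_invalid")
  expect_error(event_series(c(2, 1)), class = "evoked_invalid")
  expect_error(hypnogram(0, 10, "REM"), class = "evoked_invalid")
  expect_error(hypnogram(c(0, 5), c(10, 15), c("WAKE", "SWS")),
               class = "evoked_invalid")
  expect_error(spike_train(c(0.2, 0.1)), class = "evoked_invalid")
  rec <- cont_rec(1:100, rate = 50, start_time = 2)
  expect_equal(rec_times(rec)[1], 2)
  expect_equal(rec_times(rec)[51], 2 + 50 / 50)
})

test_that("zero-phase bandpass suppresses DC, preserves the passband and
          rejects stop-band tones", {
  rec <- cont_rec(rep(3, 3000), 1000)
  out <- bandpass(rec, 1, 40)
  expect_equal(length(out$samples), 3000)
  expect_lt(max(abs(out$samples[500:2500])), 1e-3)

  t <- seq(0, 3 - 1e-3, by = 1e-3)
  s10 <- cont_rec(sin(2 * pi * 10 * t), 1000)
  rms <- function(x) sqrt(mean(x^2))
  mid <- 1000:2000
  ratio <- rms(bandpass(s10, 1, 40)$samples[mid]) / rms(s10$samples[mid])
  expect_lt(abs(ratio - 1), 0.01)

  atten <- 20 * log10(rms(bandpass(s10, 30, 75)$samples[mid]) /
                        rms(s10$samples[mid]))
  expect_lt(atten, -20)
})

test_that("bandpass validates the band and the recording length", {
  rec <- cont_rec(rnorm(1000), 100)
  expect_error(bandpass(rec, 1, 60), class = "evoked_invalid_band")
  expect_error(bandpass(rec, 10, 4), class = "evoked_invalid_band")
  expect_error(bandpass(cont_rec(rnorm(10), 100), 1, 40),
               class = "evoked_too_short")
})

test_that("bandpass is linear", {
  set.seed(31)
  x <- rnorm(2000); y <- rnorm(2000)
  f <- function(v) bandpass(cont_rec(v, 1000), 1, 40)$samples
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  # exact in exact arithmetic; the cascaded IIR recursions leave ~1e-8
  # relative float noise
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
})

test_that("epoch extraction uses half-open windows in event order and
          reports out-of-range events", {
  set.seed(5)
  rec <- cont_rec(rnorm(5000), 1000)
  ep <- extract_epochs(rec, event_series(2), c(0.5, 0.5))
  expect_equal(dim(ep), c(1L, 1000L))
  expect_equal(ep$rel_time[1], -0.5)
  expect_equal(ep$rel_time[1000], 0.499)

  ep2 <- extract_epochs(rec, event_series(c(0.1, 2)), c(0.5, 0.5))
  expect_equal(nrow(ep2$data), 1L)
  expect_equal(nrow(attr(ep2, "dropped")), 1L)
  expect_equal(attr(ep2, "dropped")$onset_s, 0.1)

  # identical signal segments give identical rows
  rec3 <- cont_rec(rep(sin(2 * pi * (0:999) / 1000), 5), 1000)
  ep3 <- extract_epochs(rec3, event_series(c(1.5, 3.5)), c(0.5, 0.5))
  expect_identical(ep3$data[1, ], ep3$data[2, ])

  expect_equal(nrow(extract_epochs(rec, event_series(numeric(0)),
                                   c(0.5, 0.5))$data), 0L)
  expect_error(extract_epochs(rec, event_series(2), c(0, 0)),
               class = "evoked_invalid_window")
})

test_that("epoching does not resample: concatenated epochs reproduce the
          raw samples bit-exactly", {
  set.seed(6)
  rec <- cont_rec(rnorm(3000), 1000)
  ev <- event_series(c(0.5, 1.5, 2.5))
  ep <- extract_epochs(rec, ev, c(0.5, 0.5))
  expect_identical(as.numeric(t(ep$data)), rec$samples)
})

test_that("trial exclusion applies the artifact and single-state rules with
          named reasons and is idempotent", {
  set.seed(7)
  rec <- cont_rec(rnorm(4000), 1000)
  hyp <- hypnogram(c(0, 2), c(2, 3.0), c("WAKE", "SWS"))
  ev <- event_series(c(0.7, 1.8, 2.6, 3.6), artifact = c(FALSE, FALSE,
                                                         TRUE, FALSE))
  ep <- extract_epochs(rec, ev, c(0.5, 0.4))
  out <- exclude_trials(ep, hyp, ev)
  exc <- attr(out, "exclusions")
  expect_equal(nrow(out$data) + nrow(exc), nrow(ep$data))
  expect_equal(out$trial_state, "WAKE")          # trial at 0.7 only
  expect_setequal(exc$reason, c("state_change", "artifact", "unstaged"))
  expect_equal(exc$reason[exc$onset_s == 1.8], "state_change")
  expect_equal(exc$reason[exc$onset_s == 2.6], "artifact")
  expect_equal(exc$reason[exc$onset_s == 3.6], "unstaged")

  # idempotent on the retained set
  out2 <- exclude_trials(out, hyp, ev)
  expect_identical(out2$data, out$data)
  expect_equal(nrow(attr(out2, "exclusions")), 0L)
})

test_that("per-trial baseline z-scoring uses each trial's own statistics", {
  rate <- 1000
  rel <- seq(-0.5, 0.499, by = 1e-3)
  # row 1: baseline N(0,1) -> nearly unchanged; row 2: constant 5 with unit
  # noise, post-stimulus step to 7 -> post mean approx +2 z
  set.seed(8)
  noise <- rnorm(length(rel))
  row1 <- noise
  row2 <- 5 + noise + 2 * (rel >= 0)
  ep <- epoch_matrix(rbind(row1, row2), rel, rate)
  z <- zscore_to_baseline(ep, c(-0.5, 0))
  bsel <- rel < 0
  for (i in 1:2) {
    expect_lt(abs(mean(z$data[i, bsel])), 1e-9)
    expect_lt(abs(sd(z$data[i, bsel]) - 1), 1e-9)
  }
  expect_lt(abs(mean(z$data[2, !bsel]) - mean(z$data[1, !bsel]) - 2 /
                  sd(noise[bsel])), 0.05)

  flat <- epoch_matrix(rbind(rep(1, 1000)), rel, rate)
  expect_error(zscore_to_baseline(flat), class = "evoked_degenerate")
})

test_that("linear detrending removes constants and ramps and leaves
          sinusoids intact", {
  rate <- 1000
  rel <- seq(0, 0.999, by = 1e-3)
  const <- rep(5, length(rel))
  ramp <- 3 * rel
  # integer number of cycles, even-symmetric about the window centre, so the
  # least-squares line through the pure sinusoid is exactly zero
  sine <- cos(2 * pi * 40 * (rel - 0.4995))
  ep <- epoch_matrix(rbind(const, ramp, sine + ramp), rel, rate)
  out <- detrend_trials(ep, c(0, 1))
  expect_lt(max(abs(out$data[1, ])), 1e-10)
  expect_lt(max(abs(out$data[2, ])), 1e-10)
  mid <- 100:900
  expect_lt(max(abs(out$data[3, mid] - sine[mid])), 1e-8)
  expect_error(detrend_trials(ep, c(0, 0.002)),
               class = "evoked_invalid_window")
})
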