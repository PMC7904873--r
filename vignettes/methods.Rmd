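---
title: "Detecting state-dependent evoked activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting state-dependent evoked activity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evokedstate)
```

## The scientific problem

Chronic recordings in behaving animals make it possible to ask whether a
cortical area processes visceral signals differently in wakefulness and in
slow wave sleep (SWS). The experimental design this package supports pairs
two stimulation directions: electrical stimulation of the intestinal wall
while recording cortical local field potentials (LFP) and single-unit
spiking, and electrical microstimulation of the cortex while recording
duodenal myoelectric activity. Around both sits the bookkeeping that makes
such comparisons valid: vigilance staging from EEG band power, exclusion of
trials that straddle state transitions or coincide with movement artifacts,
and a check that the stimulation itself does not wake the animal.

`evokedstate` implements each of those analyses as composable functions over
a small set of containers (`cont_rec`, `event_series`, `hypnogram`,
`spike_train`, `epoch_matrix`), together with seed-controlled generators
that emulate every signal class, so the full pipeline can be validated
against known ground truth — the original animal recordings are not publicly
deposited, and nothing in this package depends on them.

## Evoked LFP detection: the residual orthogonality test

Averaging reveals an evoked potential but gives no calibrated decision rule
at a single site. The residual orthogonality test (ROT) turns trial
consistency into a test statistic. After restricting each trial $x_i(t)$ to
the analysis window and removing its least-squares line, form for every
unordered trial pair the product-sum

$$ s_{ij} \;=\; \sum_t x_i(t)\,x_j(t), \qquad i < j . $$

If the trials share a common waveform $a(t)$, every $s_{ij}$ is shifted by
$\lVert a\rVert^2 > 0$; trial-incoherent fluctuations scatter the $s_{ij}$
around zero. The mean of the $N(N-1)/2$ pair sums is compared to zero with a
one-sample $t$ test. The pair sums are uncorrelated under the null (the
cross-covariance factorizes over independent trials and vanishes for
zero-mean noise), though not independent; we follow the cited procedure in
treating them as exchangeable, and the measured null rejection rate at
$\alpha = 0.05$ (30 trials, 500 ms windows) sits inside the binomial band
around 5 %, so the approximation is calibrated in practice.

Decisions made where the procedure was underspecified:

* **Sidedness.** Detection keys on a *positive* mean, so the verdict uses
  the one-sided $p$; the two-sided value is also reported.
* **Detrending** is linear per trial inside the test window.
* **Window.** 40–540 ms after stimulus onset: 500 ms of response, starting
  after the stimulation-artifact blanking. All windows in the package are
  half-open on the sample grid, with onset belonging to the post-stimulus
  side.
* **Pair sums are unnormalized**; the scale cancels in $t$, and a
  per-sample version is reported for interpretability.

Amplitude comparison between states (`compare_peak_amplitude()`) is gated on
both states being ROT-responsive. Trials are z-scored to their own 500 ms
pre-stimulus baseline first — SWS raises background LFP amplitude (delta
waves), and without per-trial standardization that alone would inflate sleep
response amplitudes. The per-state peak is the absolute extremum of the
averaged z-curve (responses may be negative-going); each trial is averaged
over the 40 ms window centred there, oriented along the state's own response
polarity, and the two per-trial samples meet in a Wilcoxon rank-sum test.

## Spike responses: kernel density and the deviation rule

Spike times are convolved per trial with a unit-mass Gaussian kernel
($\sigma$ = 20 ms, truncated at $\pm 4\sigma$ and renormalized on the 1 ms
grid — renormalization keeps the integral of the rate curve equal to the
spike count to better than $10^{-6}$). The $\upsilon$ = 20 ms of the source
procedure is read as the kernel SD, the conventional parameterization for
spike-density kernels. The mean curve is the trial average; baseline mean
and SD come from the mean curve over the 500 ms before onset, with a floor
of 0.1 spikes/s guarding near-silent baselines and an exactly zero SD
yielding a flagged, non-significant call.

A response is significant when the mean curve deviates from the baseline
mean by more than 3 SD at a point lying inside a contiguous run of at least
30 ms during which it stays at least 2 SD away, the run falling inside
40–500 ms post-stimulus. Sign is excitatory/inhibitory when all qualifying
runs deviate one way, dual when both directions occur; onset latency is the
first 3 SD crossing of the earliest qualifying run. Runs are evaluated on
the 1 ms grid with no gap tolerance.

**A calibration caveat that matters.** This rule's false-positive rate on
homogeneous Poisson input is about 20–30 %, essentially independent of the
trial count. The cause is structural: the smoothed mean curve has a
correlation length of roughly 50 ms, so the 500 ms baseline yields only
about ten effective samples for the SD estimate, and any 3 SD excursion of
so smooth a curve automatically satisfies the 30 ms persistence requirement
— persistence only disciplines *independent* bins. The alternative reading
of the baseline SD (pooled single-trial variability) drives false positives
to zero but makes inhibitory responses undetectable at any realistic firing
rate, because a rate cannot fall below zero while three single-trial SDs
exceed the baseline itself; since inhibitory responses are an expected
outcome class, the averaged-curve reading is the only coherent one. The
package therefore implements the rule as published and *measures* its
false-alarm behaviour in the test suite rather than asserting an analytic
level. Users should treat single-cell verdicts as descriptive and rely on
population contrasts (below) for inference; detected-versus-true confusion
on synthetic data is dominated by null cells being promoted, not by
responsive cells being missed or mis-signed.

Cells are classified from their two state calls: exclusively
sleep-responsive, exclusively wake-responsive, both with opposite signs
(dual counts as different from either pure sign), both with the same sign,
or unresponsive; when both calls are significant the onset latencies are
additionally compared against a 50 ms difference.

## Vigilance staging and the disturbance test

Band powers come from multitaper spectral estimation with 5 Slepian tapers
and time–bandwidth product NW = 3. No installed R package provides discrete
prolate spheroidal sequences, so the package computes them from the standard
symmetric tridiagonal eigenproblem using Sturm-sequence bisection plus
tridiagonal inverse iteration — $O(N)$ per taper, cached per segment length
— with exact band concentrations obtained by applying the sinc kernel via
circulant embedding. The tapers match `scipy.signal.windows.dpss` to at
least seven digits (frozen in the tests), and the eigenvalue-weighted
estimate is normalized so the one-sided PSD integrates to the segment
variance.

Staging validation (`compare_states()`) tiles each hypnogram interval with
non-overlapping 10 s windows (the same length as the disturbance windows;
the staging window length was an open choice), integrates the PSD over
delta (1–4 Hz), spindle (7–14 Hz) and gamma (30–75 Hz) bands and rank-sums
SWS against WAKE per band. A 50 Hz notch is available but off by default —
synthetic data carry no line noise.

The disturbance test compares band powers between the 10 s before and the
10 s after each stimulus (windows abut the stimulus with the stimulus sample
excluded; whether the source procedure skipped the 12 ms artifact blanking
is unstated, and at 10 s windows the difference is immaterial), with paired
signed-rank tests per band at $\alpha$ = 0.05 per band and no multiplicity
correction in the per-band report. For the single *awakening* verdict the
package requires a significant gamma increase, or a significant decrease in
both slow bands (delta *and* spindles). A fully disjunctive verdict over
three band-direction tests would carry a ~7 % structural false-alarm rate
under the null — three uncorrected chances to "wake" the animal — whereas
true cortical arousal raises gamma and lowers both slow bands together;
requiring either the gamma signature or the concordant slow-band signature
keeps single-band recovery intact (an injected pure gamma rise is still
called an awakening) while bringing the null false-alarm rate to ~2.5 %.
A Bonferroni-corrected verdict is also emitted. Significant changes in the
somnogenic direction (delta or spindle increase, gamma decrease) are flagged
separately as `somnogenic_hint`.

## Duodenal myoelectric responses

Two frequency bands carry distinct physiology: simple waves (electrical
control activity) concentrate below 2 Hz and set contraction timing;
spike-potentials (electrical response activity, 3–10 Hz) ride on some slow
waves and mark actual contractions. The simple-wave test compares multitaper
band power in the 40 s before onset against the 40 s starting 0.5 s after
onset, paired across events (signed-rank). The spike-potential test needs a
reference point: the package band-limits the post-stimulus window to the
simple-wave band, takes the analytic-signal magnitude smoothed with a 5 s
moving average as the modulation envelope (no envelope estimator was named
in the source; the analytic signal is the standard choice), and centres a
20 s window at the envelope maximum — or minimum when the session-level
simple-wave change was a decrease. The pre-stimulus comparison window is
time-mirrored about the onset, read literally from "at the same distance
before the stimulus"; extrema closer than 10.5 s are clamped so the window
stays post-stimulus. Multitaper parameters are reused from the EEG analysis
(NW = 3, K = 5); nothing suggested different taper settings for the gut
windows. The spike-potential analysis is always computed; reporting it only
for sessions with a significant simple-wave change is a caller-side filter,
and `glance()` exposes both p-values.

## Population statistics

Site-level and cell-level state contrasts use the exact hypergeometric test
implemented by direct enumeration (`fisher_exact_2x2()`), cross-checked in
the tests against `stats::fisher.test` to $10^{-12}$. On the published
site table — 15 of 30 sites responsive in sleep versus 6 of 30 in
wakefulness — the *directional* exact p-value is 0.0146, matching the
printed 0.015; the two-sided probability-mass value is 0.029. The site
report therefore presents both, headlining the directional test, which is
also the question actually asked (is the sleep proportion *higher*). For
the per-animal excess of exclusively sleep-responsive cells the published
construction is ambiguous, so the report computes two clearly labelled
candidates: an unpaired exact test of exclusive counts against totals, and
an exact binomial test on the discordant pair; neither is asserted to be
the published one.

## The synthetic-data generators

The generators define the study conditions; their defaults are fixed once
and are not tuned to any test outcome.

* **Stimulus trains**: i.i.d. uniform inter-stimulus intervals, 45–60 s for
  intestinal stimulation. Gut sessions instead default to ~120 s ISIs, the
  cortical-microstimulation protocol of the animal whose duodenal signal
  was recorded; a 40 s post-stimulus effect inside a 45–60 s ISI would
  bleed into the next trial's pre-window, which the published windowing
  presupposes cannot happen.
* **EEG**: a sum over bands of band-limited unit-variance Gaussian noise
  with per-state gains (defaults: SWS doubles delta and spindle amplitude
  and halves gamma), switching at hypnogram boundaries. Band power scales
  as gain², which the tests verify through the full multitaper path.
* **Evoked LFP**: 1/f Gaussian background (spectral synthesis, exponent 1 —
  colored noise stresses the detrending step in a way white noise would
  not) plus an alpha-function kernel $(s/\tau)e^{1-s/\tau}$,
  $\tau$ = duration/5, at each effective stimulus; biphasic for dual
  responses. The kernel shape is a simulation choice, not a claim about
  cortical biophysics — it is smooth, causal and parameterized by exactly
  latency/amplitude/duration.
* **Spike trains**: inhomogeneous Poisson by thinning; excitatory specs
  scale the baseline rate by $1 + a\,k(t)$, inhibitory by
  $\max(0, 1 - a\,k(t))$, with a warning when a modulation is clipped at
  zero.
* **Gut signal**: a 0.3 Hz slow-wave carrier (a plausible duodenal rate;
  the source states no value) with lognormally varying amplitude
  (~20 s correlation), burst packets of 3–10 Hz noise snapped to slow-wave
  crests at 4–5 per minute, low-level white measurement noise, and optional
  post-stimulus multiplicative changes of slow-wave amplitude and burst
  rate in the stimulated state.

What the generators do *not* emulate: non-Poisson spiking statistics
(bursting, refractoriness), non-stationary background EEG within a state,
REM sleep, movement artifacts with realistic waveforms (artifacts exist
only as flags), electrode drift, and line noise. Passing recovery tests on
these generators therefore demonstrates correctness of the *procedures*,
not robustness to every pathology of real recordings.

## Numerical choices and degenerate inputs

* Zero-phase filtering is Butterworth (4th-order sections) run forward and
  backward with odd-reflection end padding of about three time constants of
  the band edge, so start-up transients decay outside the data. Band-pass
  is a high-pass/low-pass cascade: direct-form band-pass coefficients
  become ill-conditioned when the lower edge is a tiny fraction of the
  Nyquist frequency (0.3 Hz on a 10 kHz recording).
* Epoching never resamples; trials are matched to events by index, and
  mismatched lengths are an error rather than a silent truncation.
* Constant trials make baseline z-scoring impossible and raise a classed
  error naming the trial; a zero baseline SD in spike detection produces a
  flagged non-significant call instead.
* Signed-rank and rank-sum tests need minimum sample sizes to be able to
  reject at all; event-paired analyses require at least 6 usable events
  (the smallest n whose exact two-sided signed-rank p can fall below 0.05)
  and staging requires 3 windows per state.
* All randomness flows from explicit seeds; generators are pure functions
  of (parameters, seed), and derived child seeds stay below $2^{31}$.

## Problem sizes used in the checks

The test suite and the reproduction script run the procedures at the sizes
the analyses were designed for — 30 trials per state for the trial-level
tests, 30+ staging windows per state, 25 stimulation events for the
injected myoelectric effect — and use 100–1000 Monte-Carlo replicates for
calibration curves (null rejection rates, detection power), which bounds
every rate estimate's standard error at a few percentage points while
keeping the whole suite inside a few minutes on one CPU.

## Known limitations

* The spike-response rule's high intrinsic false-alarm rate (above) is a
  property of the published criterion, reproduced faithfully; this package
  measures it instead of hiding it.
* The ROT treats dependent pair sums as exchangeable; the t reference is an
  approximation, good at the sizes tested.
* EDF ingestion is not implemented; recordings enter as delimited text with
  strict uniform-sampling validation.
* The pipeline analyzes one recording site / one gut channel per call;
  multi-site studies iterate (`simulate_lfp_study()` shows the pattern).
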