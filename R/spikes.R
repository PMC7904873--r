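#' Peristimulus spike-density (rate) curve
#'
#' Per trial, the spike times inside the window are convolved with a
#' unit-area Gaussian kernel (SD `sigma`, truncated at +/- 4 sigma and
#' renormalized to unit mass on the grid) sampled on a 1 ms grid; the mean
#' curve is the trial average. Baseline mean and SD are taken from the mean
#' curve over the 500 ms before stimulus onset.
#'
#' @param train A [spike_train()].
#' @param events An [event_series()]; trials are cut at every non-flagged
#'   onset.
#' @param window Relative window `c(t0, t1)` in seconds; must cover at least
#'   `(-0.5, 0.5)`.
#' @param sigma Gaussian kernel SD in seconds (default 0.020 s).
#' @param baseline Baseline window, default `c(-0.5, 0)`.
#' @return An object of class `rate_curve`: `rel_time` (1 ms grid), `mean`
#'   (spikes/s), `trial_rates` (trials x grid matrix), `n_trials`,
#'   `baseline_mean`, `baseline_sd`, `sigma`.
#' @examples
#' hyp <- gen_hypnogram("SWS", 300)
#' ev <- gen_stim_times(hyp, c(10, 12), seed = 2)
#' tr <- gen_spikes(hyp, ev, baseline_hz = 10, seed = 2)
#' rc <- spike_density(tr, ev)
#' rc$baseline_mean
#' @export
spike_density <- function(train, events, window = c(-0.5, 0.5),
                          sigma = 0.020, baseline = c(-0.5, 0)) {
  if (sigma <= 0) stop_evoked("evoked_invalid", "sigma must be positive")
  if (window[1] > -0.5 || window[2] < 0.5) {
    stop_evoked("evoked_invalid_window", "window must cover (-0.5, 0.5) s")
  }
  onsets <- events$onset_s[!events$artifact]
  if (!length(onsets)) stop_evoked("evoked_insufficient", "no trials")
  dt <- 0.001
  grid <- seq(window[1], window[2] - dt / 2, by = dt)
  ng <- length(grid)
  half <- as.integer(ceiling(4 * sigma / dt))
  kern <- dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / (sum(kern) * dt)          # unit area on the grid
  # bin spikes (with kernel margin) and convolve via FFT per trial
  nbin <- ng + 2L * half
  nfft <- stats::nextn(nbin + 2L * half + 1L, 2L)
  kpad <- numeric(nfft)
  kpad[1:(2L * half + 1L)] <- kern
  fk <- stats::fft(kpad)
  counts <- matrix(0, nfft, length(onsets))
  for (j in seq_along(onsets)) {
    rel <- train$time_s - onsets[j]
    rel <- rel[rel >= window[1] - half * dt & rel < window[2] + half * dt]
    if (length(rel)) {
      b <- as.integer(round((rel - window[1]) / dt)) + half + 1L
      b <- b[b >= 1L & b <= nbin]
      counts[, j] <- counts[, j] + tabulate(b, nbins = nfft)
    }
  }
  conv <- Re(stats::mvfft(stats::mvfft(counts) * fk, inverse = TRUE)) / nfft
  # kernel is centered at lag `half` within kpad; bin b sits at grid index
  # b - half, so row offset is 2 * half
  rates <- t(conv[(2L * half + 1L):(2L * half + ng), , drop = FALSE])
  mean_rate <- colMeans(rates)
  bsel <- grid >= baseline[1] & grid < baseline[2]
  structure(
    list(rel_time = grid, mean = mean_rate, trial_rates = rates,
         n_trials = length(onsets), baseline_mean = mean(mean_rate[bsel]),
         baseline_sd = sd(mean_rate[bsel]), baseline_window = baseline,
         sigma = sigma),
    class = "rate_curve"
  )
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf(
    "<rate_curve> %d trials, sigma = %g ms; baseline %.2f +/- %.2f spikes/s\n",
    x$n_trials, x$sigma * 1000, x$baseline_mean, x$baseline_sd))
  invisible(x)
}

#' @export
as_tibble.rate_curve <- function(x, ...) {
  tibble(rel_time = x$rel_time, rate = x$mean)
}

#' Rule-based detection of a stimulus-locked rate response
#'
#' The averaged rate curve is significant when it deflects beyond three
#' baseline SDs at some point that lies inside a contiguous run of at least
#' 30 ms during which it stays at least two baseline SDs away from the
#' baseline mean, with the run inside the 40-500 ms post-stimulus window.
#' The response sign is excitatory if every qualifying run is positive,
#' inhibitory if every run is negative, and dual when both occur; onset
#' latency is the first three-SD crossing of the earliest qualifying run.
#' A floor of `sd_floor` (default 0.1 spikes/s) guards near-silent
#' baselines; a baseline SD of exactly zero yields a non-significant,
#' degenerate-flagged call.
#'
#' @param curve A [spike_density()] rate curve.
#' @param analysis_window Post-stimulus window, default `c(0.040, 0.500)` s.
#' @param min_run_s Minimum persistent deviation (default 0.030 s).
#' @param sd_floor Baseline-SD floor in spikes/s.
#' @return An object of class `response_call`: `significant`, `sign`
#'   (`"excitatory"`, `"inhibitory"`, `"dual"`, `"none"`), `onset_latency_s`,
#'   `deviations` (tibble of qualifying runs), `degenerate`.
#' @export
detect_response <- function(curve, analysis_window = c(0.040, 0.500),
                            min_run_s = 0.030, sd_floor = 0.1) {
  stopifnot(inherits(curve, "rate_curve"))
  none <- function(flag = FALSE) structure(
    list(significant = FALSE, sign = "none", onset_latency_s = NA_real_,
         deviations = tibble(start_s = numeric(0), end_s = numeric(0),
                             sign = character(0)),
         degenerate = flag, analysis_window = analysis_window),
    class = "response_call")
  if (!is.finite(curve$baseline_sd) || curve$baseline_sd == 0) {
    return(none(flag = TRUE))
  }
  sdv <- max(curve$baseline_sd, sd_floor)
  sel <- which(curve$rel_time >= analysis_window[1] &
                 curve$rel_time < analysis_window[2])
  t <- curve$rel_time[sel]
  dev <- curve$mean[sel] - curve$baseline_mean
  dt <- t[2] - t[1]
  over2 <- abs(dev) >= 2 * sdv
  runs <- rle(over2)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qual <- tibble(start_s = numeric(0), end_s = numeric(0), sign = character(0),
                 onset_s = numeric(0))
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    if ((i1 - i0 + 1L) * dt < min_run_s) next
    seg <- dev[i0:i1]
    hit3 <- which(abs(seg) > 3 * sdv)
    if (!length(hit3)) next
    qual <- dplyr::bind_rows(qual, tibble(
      start_s = t[i0], end_s = t[i1] + dt,
      sign = if (seg[hit3[1]] > 0) "positive" else "negative",
      onset_s = t[i0 + hit3[1] - 1L]))
  }
  if (nrow(qual) == 0L) return(none())
  sgn <- unique(qual$sign)
  structure(
    list(significant = TRUE,
         sign = if (length(sgn) > 1L) "dual"
                else if (sgn == "positive") "excitatory" else "inhibitory",
         onset_latency_s = min(qual$onset_s),
         deviations = qual[, c("start_s", "end_s", "sign")],
         degenerate = FALSE, analysis_window = analysis_window),
    class = "response_call"
  )
}

#' @export
print.response_call <- function(x, ...) {
  if (!x$significant) {
    cat("<response_call> not significant",
        if (x$degenerate) "(degenerate baseline)", "\n")
  } else {
    cat(sprintf("<response_call> %s, onset %.0f ms, %d deviation run(s)\n",
                x$sign, x$onset_latency_s * 1000, nrow(x$deviations)))
  }
  invisible(x)
}

#' @export
tidy.response_call <- function(x, ...) {
  tibble(significant = x$significant, sign = x$sign,
         onset_latency_s = x$onset_latency_s,
         n_deviations = nrow(x$deviations), degenerate = x$degenerate)
}

#' Classify a cell from its sleep and wake response calls
#'
#' Five-way classification: exclusively sleep-responsive, exclusively
#' wake-responsive, responsive in both states with opposite signs (a dual
#' response counts as different from either pure sign), responsive in both
#' with the same sign, or unresponsive. When both calls are significant the
#' onset-latency difference is compared against 50 ms.
#'
#' @param call_sleep,call_wake [detect_response()] calls for the same unit.
#' @return A tibble row of class `cell_category`: `category`,
#'   `latency_differs`, `sign_sleep`, `sign_wake`.
#' @export
classify_cell <- function(call_sleep, call_wake) {
  s <- call_sleep$significant
  w <- call_wake$significant
  category <- if (s && w) {
    if (call_sleep$sign != call_wake$sign) "both_opposite" else "both_same"
  } else if (s) "sleep_only" else if (w) "wake_only" else "none"
  latency_differs <- if (s && w) {
    abs(call_sleep$onset_latency_s - call_wake$onset_latency_s) > 0.050
  } else NA
  out <- tibble(category = category, latency_differs = latency_differs,
                sign_sleep = call_sleep$sign, sign_wake = call_wake$sign)
  class(out) <- c("cell_category", class(out))
  out
}

#' Tabulate cell categories into a summary table
#'
#' Counts cells per response category per group (e.g., per animal), in the
#' shape of a responders breakdown: recorded, responded, exclusively
#' sleep-responsive, exclusively wake-responsive, both-opposite, both-same.
#' Responders are all categories except `"none"`; the partition
#' `sleep_only + wake_only + both_opposite + both_same = responded` holds by
#' construction.
#'
#' @param categories A tibble with a `category` column (rows = cells), e.g.
#'   row-bound [classify_cell()] results.
#' @param group Optional group label per cell (defaults to one group).
#' @return A tibble with one row per group and count columns.
#' @export
tabulate_cells <- function(categories, group = NULL) {
  cat_levels <- c("sleep_only", "wake_only", "both_opposite", "both_same",
                  "none")
  cats <- categories$category
  if (!all(cats %in% cat_levels)) {
    stop_evoked("evoked_invalid", "unknown category label")
  }
  grp <- group %||% rep("all", length(cats))
  df <- tibble(group = as.character(grp),
               category = factor(cats, levels = cat_levels))
  out <- df |>
    dplyr::count(.data$group, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n") |>
    dplyr::mutate(
      recorded = .data$sleep_only + .data$wake_only + .data$both_opposite +
        .data$both_same + .data$none,
      responded = .data$recorded - .data$none) |>
    dplyr::select("group", "recorded", "responded", "sleep_only",
                  "wake_only", "both_opposite", "both_same", "none")
  stopifnot(all(out$responded == out$sleep_only + out$wake_only +
                  out$both_opposite + out$both_same))
  out
}
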