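#' Compare band power between sleep and wakefulness
#'
#' Tiles every hypnogram interval with non-overlapping `window_s` segments,
#' computes multitaper band powers per segment ([multitaper_psd()], 5 Slepian
#' tapers, NW = 3 by default) and compares SWS against WAKE per band with
#' the Wilcoxon rank-sum test. This is the quantitative staging validation:
#' in slow wave sleep delta and spindle power are higher while gamma power
#' is higher in wakefulness.
#'
#' @param rec A [cont_rec()] (EEG or LFP).
#' @param hyp A [hypnogram()].
#' @param bands A [band_set()].
#' @param window_s Segment length in seconds (default 10).
#' @param NW,K Multitaper parameters.
#' @param alpha Significance level for the reported direction.
#' @return A tibble with one row per band: `band`, `n_sws`, `n_wake`,
#'   `median_sws`, `median_wake`, `statistic`, `p_value`, `direction`
#'   (`"higher_in_sws"`, `"higher_in_wake"` or `"none"`).
#' @export
compare_states <- function(rec, hyp, bands = band_set(), window_s = 10,
                           NW = 3, K = 5L, alpha = 0.05) {
  pows <- state_window_powers(rec, hyp, bands, window_s, NW, K)
  for (st in c("SWS", "WAKE")) {
    if (length(unique(pows$window_start_s[pows$state == st])) < 3L) {
      stop_evoked("evoked_insufficient",
                  sprintf("fewer than 3 %s windows of %g s", st, window_s))
    }
  }
  purrr::map_dfr(bands$band, function(b) {
    x <- pows[pows$band == b & pows$state == "SWS", ]$power
    y <- pows[pows$band == b & pows$state == "WAKE", ]$power
    wt <- suppressWarnings(wilcox.test(x, y))
    dir <- "none"
    if (wt$p.value < alpha) {
      dir <- if (median(x) > median(y)) "higher_in_sws" else "higher_in_wake"
    }
    tibble(band = b, n_sws = length(x), n_wake = length(y),
           median_sws = median(x), median_wake = median(y),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           direction = dir)
  })
}

# Band powers of all complete non-overlapping windows per hypnogram interval.
state_window_powers <- function(rec, hyp, bands, window_s, NW = 3, K = 5L) {
  rows <- list()
  for (i in seq_len(nrow(hyp))) {
    t0 <- max(hyp$start_s[i], rec$start_time)
    t1 <- min(hyp$end_s[i], rec_end(rec))
    nwin <- floor((t1 - t0) / window_s)
    if (nwin < 1L) next
    for (w in seq_len(nwin)) {
      seg <- rec_slice(rec, t0 + (w - 1) * window_s, t0 + w * window_s)
      bp <- segment_band_powers(seg, bands, NW, K)
      rows[[length(rows) + 1L]] <- tibble(
        state = hyp$state[i], window_start_s = t0 + (w - 1) * window_s,
        band = bands$band, power = bp)
    }
  }
  if (!length(rows)) {
    stop_evoked("evoked_insufficient", "no complete staging windows")
  }
  dplyr::bind_rows(rows)
}

#' Test for stimulation-induced sleep disturbance
#'
#' Compares band power between the 10 s before and the 10 s after every
#' stimulus (the stimulus instant itself is excluded) with a paired Wilcoxon
#' signed-rank test per band. An awakening signature is a drop in the slow
#' bands together with a gamma rise; the verdict is `awakening = TRUE` when
#' gamma increases significantly, or when both delta and spindle power
#' decrease significantly. A significant change in the opposite direction
#' (delta or spindle increase, or gamma decrease) is flagged as
#' `somnogenic_hint`. A Bonferroni-corrected awakening verdict (alpha / 3
#' per band) is also reported.
#'
#' @param rec A [cont_rec()].
#' @param events An [event_series()].
#' @param hyp A [hypnogram()]; events are used only if their pre and post
#'   windows stay inside a single interval (optionally of `state`).
#' @param bands A [band_set()].
#' @param pre_post_s Window length on each side of the stimulus (default 10).
#' @param state Optional state filter (e.g. `"SWS"` to ask whether sleep
#'   was disturbed).
#' @param NW,K Multitaper parameters.
#' @param alpha Per-band significance level.
#' @return An object of class `disturbance_verdict`: per-band tibble
#'   (`band`, `n_pairs`, `statistic`, `p_value`, `direction`), `awakening`,
#'   `awakening_bonferroni`, `somnogenic_hint`, `n_events_used`,
#'   `n_events_dropped`.
#' @export
disturbance_test <- function(rec, events, hyp, bands = band_set(),
                             pre_post_s = 10, state = NULL, NW = 3, K = 5L,
                             alpha = 0.05) {
  onsets <- events$onset_s[!events$artifact]
  used <- numeric(0)
  for (on in onsets) {
    st <- span_state(hyp, on - pre_post_s, on + pre_post_s)
    if (is.na(st) || st == "state_change") next
    if (!is.null(state) && st != state) next
    if (on - pre_post_s < rec$start_time || on + pre_post_s > rec_end(rec)) next
    used <- c(used, on)
  }
  if (length(used) < 6L) {
    stop_evoked("evoked_insufficient",
                sprintf("only %d usable events (need >= 6)", length(used)))
  }
  dt <- 1 / rec$rate
  pre <- matrix(0, length(used), nrow(bands))
  post <- matrix(0, length(used), nrow(bands))
  for (j in seq_along(used)) {
    on <- used[j]
    pre[j, ] <- segment_band_powers(rec_slice(rec, on - pre_post_s, on),
                                    bands, NW, K)
    post[j, ] <- segment_band_powers(rec_slice(rec, on + dt, on + dt +
                                                 pre_post_s), bands, NW, K)
  }
  per_band <- purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    wt <- suppressWarnings(wilcox.test(post[, i], pre[, i], paired = TRUE))
    dir <- "none"
    if (wt$p.value < alpha) {
      dir <- if (median(post[, i] - pre[, i]) > 0) "increase" else "decrease"
    }
    tibble(band = bands$band[i], n_pairs = length(used),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           direction = dir)
  })
  verdict_at <- function(a) {
    gamma_up <- per_band$p_value[per_band$band == "gamma"] < a &&
      median(post[, 3] - pre[, 3]) > 0
    delta_dn <- per_band$p_value[per_band$band == "delta"] < a &&
      median(post[, 1] - pre[, 1]) < 0
    spin_dn <- per_band$p_value[per_band$band == "spindles"] < a &&
      median(post[, 2] - pre[, 2]) < 0
    gamma_up || (delta_dn && spin_dn)
  }
  somnogenic <- any(
    per_band$p_value < alpha &
      ((per_band$band %in% c("delta", "spindles") &
          per_band$direction == "increase") |
         (per_band$band == "gamma" & per_band$direction == "decrease")))
  structure(
    list(per_band = per_band, awakening = verdict_at(alpha),
         awakening_bonferroni = verdict_at(alpha / nrow(bands)),
         somnogenic_hint = somnogenic, n_events_used = length(used),
         n_events_dropped = length(onsets) - length(used), alpha = alpha),
    class = "disturbance_verdict"
  )
}

#' @export
print.disturbance_verdict <- function(x, ...) {
  cat(sprintf(
    "<disturbance_verdict> %d events (%d dropped): awakening = %s%s\n",
    x$n_events_used, x$n_events_dropped, x$awakening,
    if (x$somnogenic_hint) " (somnogenic hint)" else ""))
  print(x$per_band)
  invisible(x)
}

#' @export
tidy.disturbance_verdict <- function(x, ...) x$per_band

#' @export
glance.disturbance_verdict <- function(x, ...) {
  tibble(awakening = x$awakening,
         awakening_bonferroni = x$awakening_bonferroni,
         somnogenic_hint = x$somnogenic_hint,
         n_events_used = x$n_events_used,
         n_events_dropped = x$n_events_dropped)
}
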