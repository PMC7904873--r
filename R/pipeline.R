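#' Per-site evoked-LFP analysis for both states
#'
#' Epochs the LFP around non-flagged stimuli, drops trials that cross a
#' state boundary or carry artifacts, runs the residual orthogonality test
#' per state, and — when both states show a significant evoked potential —
#' compares peak amplitudes between states on the z-scored trials.
#'
#' @param rec An LFP [cont_rec()].
#' @param events An [event_series()].
#' @param hyp A [hypnogram()].
#' @param window Epoch window `c(pre_s, post_s)`; the default `c(0.5, 0.6)`
#'   covers the 500 ms baseline and the 40-540 ms test window.
#' @param test_window Residual-orthogonality window (default
#'   `c(0.040, 0.540)`).
#' @param alpha Detection level.
#' @return A list of class `lfp_site_result`: `rot` (named list of
#'   [rot_test()] results per state), `amplitude` (an
#'   [compare_peak_amplitude()] result or `NULL`), `n_trials` per state,
#'   `exclusions`.
#' @export
lfp_site_analysis <- function(rec, events, hyp, window = c(0.5, 0.6),
                              test_window = c(0.040, 0.540), alpha = 0.05) {
  ep <- extract_epochs(rec, events, window)
  ep <- exclude_trials(ep, hyp, events)
  rot <- list()
  zs <- list()
  for (st in c("SWS", "WAKE")) {
    eps <- epochs_by_state(ep, st)
    if (nrow(eps$data) >= 3L) {
      rot[[st]] <- rot_test(eps, window = test_window, alpha = alpha)
      zs[[st]] <- zscore_to_baseline(eps)
    }
  }
  amplitude <- NULL
  if (isTRUE(rot$SWS$responsive) && isTRUE(rot$WAKE$responsive)) {
    amplitude <- compare_peak_amplitude(zs$SWS, zs$WAKE,
                                        window = test_window, alpha = alpha)
  }
  structure(
    list(rot = rot, amplitude = amplitude,
         n_trials = vapply(zs, function(z) nrow(z$data), integer(1)),
         exclusions = attr(ep, "exclusions")),
    class = "lfp_site_result"
  )
}

#' @export
tidy.lfp_site_result <- function(x, ...) {
  purrr::map_dfr(names(x$rot), function(st) {
    dplyr::mutate(tidy(x$rot[[st]]), state = st, .before = 1)
  })
}

#' Per-unit spike analysis for both states
#'
#' Splits the stimuli by the state in which they were delivered (trials
#' crossing a boundary or flagged as artifacts are excluded), estimates the
#' peristimulus rate per state, applies the response criterion and
#' classifies the cell.
#'
#' @param train A [spike_train()].
#' @param events An [event_series()].
#' @param hyp A [hypnogram()].
#' @param sigma Spike-density kernel SD (s).
#' @param window Peristimulus window for the density (default
#'   `c(-0.5, 0.5)`).
#' @param analysis_window Response-criterion window (default
#'   `c(0.040, 0.500)`).
#' @return A list of class `spike_unit_result`: `curves` and `calls` per
#'   state, `category` ([classify_cell()] row).
#' @export
spike_unit_analysis <- function(train, events, hyp, sigma = 0.020,
                                window = c(-0.5, 0.5),
                                analysis_window = c(0.040, 0.500)) {
  pre_s <- -window[1]; post_s <- window[2]
  curves <- list(); calls <- list()
  for (st in c("SWS", "WAKE")) {
    keep <- !events$artifact &
      vapply(events$onset_s, function(on) {
        s <- span_state(hyp, on - pre_s, on + post_s)
        !is.na(s) && s == st
      }, logical(1))
    ev <- event_series(events$onset_s[keep])
    if (nrow(ev) == 0L) {
      calls[[st]] <- structure(
        list(significant = FALSE, sign = "none", onset_latency_s = NA_real_,
             deviations = tibble(), degenerate = TRUE,
             analysis_window = analysis_window),
        class = "response_call")
      next
    }
    curves[[st]] <- spike_density(train, ev, window = window, sigma = sigma)
    calls[[st]] <- detect_response(curves[[st]],
                                   analysis_window = analysis_window)
  }
  structure(
    list(curves = curves, calls = calls,
         category = classify_cell(calls$SWS, calls$WAKE)),
    class = "spike_unit_result"
  )
}

#' Simulate a multi-site evoked-LFP study
#'
#' Generates one synthetic session per recording site: an alternating
#' WAKE/SWS hypnogram, stimulus trains at the interstimulus interval of the
#' intestinal protocol, and an LFP with a state-dependent evoked component
#' according to the site's ground-truth responsiveness.
#'
#' @param n_sites Number of sites.
#' @param sleep_responsive,wake_responsive Logical vectors (length
#'   `n_sites`) of ground-truth responsiveness per state.
#' @param amplitude Evoked amplitude in noise-SD units (high SNR default 5).
#' @param isi Interstimulus interval range in seconds.
#' @param block_s Duration of each WAKE/SWS block (four blocks per session).
#' @param rate LFP sampling rate (down-scaled default 500 Hz).
#' @param seed Base seed; site `i` uses a derived child seed.
#' @return A tibble with `site`, `state`, `pair_mean`, `p_value`,
#'   `responsive`, `truth`.
#' @export
simulate_lfp_study <- function(n_sites = 30,
                               sleep_responsive = rep(c(TRUE, FALSE),
                                                      c(15, 15)),
                               wake_responsive = rep(c(TRUE, FALSE),
                                                     c(6, 24)),
                               amplitude = 5, isi = c(45, 60),
                               block_s = 600, rate = 500, seed = 1) {
  rows <- list()
  for (i in seq_len(n_sites)) {
    s <- child_seed(seed, i)
    hyp <- gen_hypnogram(c("WAKE", "SWS", "WAKE", "SWS"), rep(block_s, 4))
    ev <- gen_stim_times(hyp, isi, seed = s)
    specs <- evoked_spec()[0, ]
    if (sleep_responsive[i]) {
      specs <- dplyr::bind_rows(specs, evoked_spec(
        latency_s = 0.12, amplitude = amplitude, duration_s = 0.25,
        sign = "excitatory", state = "SWS"))
    }
    if (wake_responsive[i]) {
      specs <- dplyr::bind_rows(specs, evoked_spec(
        latency_s = 0.12, amplitude = amplitude * 0.6, duration_s = 0.25,
        sign = "excitatory", state = "WAKE"))
    }
    rec <- gen_lfp_evoked(hyp, ev, specs, rate = rate, seed = s + 1L)
    res <- lfp_site_analysis(rec, ev, hyp)
    for (st in names(res$rot)) {
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        tidy(res$rot[[st]]),
        site = i, state = st,
        truth = if (st == "SWS") sleep_responsive[i] else wake_responsive[i],
        .before = 1)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a cell-classification study with known category counts
#'
#' Generates one synthetic unit per cell with stimulus-locked rate
#' modulation matching its ground-truth category (high-SNR defaults), runs
#' the full spike pipeline ([spike_unit_analysis()]) and returns detected
#' against true categories. Cells classified `sleep_only` respond only
#' during slow wave sleep, `both_opposite` cells flip sign between states,
#' etc.
#'
#' @param counts Named integer vector with entries `sleep_only`,
#'   `wake_only`, `both_opposite`, `both_same`, `none`.
#' @param group Group label attached to every cell.
#' @param n_trials Stimuli per state.
#' @param baseline_hz Baseline firing rate (both states).
#' @param amplitude Peak fractional rate modulation for responsive states.
#' @param seed Base seed.
#' @return A tibble with `cell`, `group`, `truth`, `category` (detected),
#'   plus the per-state detected signs.
#' @export
simulate_cell_study <- function(counts = c(sleep_only = 24, wake_only = 4,
                                           both_opposite = 6, both_same = 1,
                                           none = 32),
                                group = "cat1", n_trials = 30,
                                baseline_hz = 20, amplitude = 4, seed = 1) {
  truth <- rep(names(counts), counts)
  rows <- list()
  isi <- c(8, 10)   # compressed ISI: trials are independent 1 s epochs
  block_s <- n_trials * mean(isi) + 20
  hyp <- gen_hypnogram(c("WAKE", "SWS"), rep(block_s, 2))
  for (i in seq_along(truth)) {
    s <- child_seed(seed, i)
    ev <- gen_stim_times(hyp, isi, seed = s)
    specs <- switch(
      truth[i],
      sleep_only = evoked_spec(0.12, amplitude, 0.2, "excitatory", "SWS"),
      wake_only = evoked_spec(0.12, amplitude, 0.2, "excitatory", "WAKE"),
      both_opposite = dplyr::bind_rows(
        evoked_spec(0.12, amplitude, 0.2, "excitatory", "SWS"),
        evoked_spec(0.12, 0.95, 0.25, "inhibitory", "WAKE")),
      both_same = dplyr::bind_rows(
        evoked_spec(0.12, amplitude, 0.2, "excitatory", "SWS"),
        evoked_spec(0.12, amplitude, 0.2, "excitatory", "WAKE")),
      none = evoked_spec()[0, ])
    tr <- gen_spikes(hyp, ev, baseline_hz = baseline_hz, specs = specs,
                     seed = s + 1L, unit_id = sprintf("%s_c%03d", group, i))
    res <- spike_unit_analysis(tr, ev, hyp)
    rows[[i]] <- dplyr::mutate(res$category, cell = i, group = group,
                               truth = truth[i], .before = 1)
  }
  dplyr::bind_rows(rows)
}

#' Simulation run configuration
#'
#' Bundles input paths and analysis parameters for [run_pipeline()].
#' Parameters are validated up front; the configuration round-trips to
#' JSON/YAML losslessly.
#'
#' @param paths Named list of input files; recognized names: `eeg`, `lfp`,
#'   `gut`, `spikes`, `events`, `hypnogram`. Stages run only when their
#'   inputs are present.
#' @param alpha Detection level.
#' @param epoch_window,test_window LFP windows (s).
#' @param sigma Spike-density kernel SD (s).
#' @param bands A [band_set()].
#' @param myo A [myo_windows()].
#' @param staging_window_s,pre_post_s Vigilance windows (s).
#' @param seed Integer seed recorded with every output.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(paths = list(), alpha = 0.05,
                       epoch_window = c(0.5, 0.6),
                       test_window = c(0.040, 0.540), sigma = 0.020,
                       bands = band_set(), myo = myo_windows(),
                       staging_window_s = 10, pre_post_s = 10, seed = 1L,
                       out_dir = tempfile("evokedstate_run_")) {
  if (alpha <= 0 || alpha >= 1) stop_evoked("evoked_invalid", "alpha in (0,1)")
  if (sigma <= 0) stop_evoked("evoked_invalid", "sigma must be positive")
  if (test_window[1] >= test_window[2]) {
    stop_evoked("evoked_invalid_window", "test window must be ordered")
  }
  unknown <- setdiff(names(paths),
                     c("eeg", "lfp", "gut", "spikes", "events", "hypnogram"))
  if (length(unknown)) {
    stop_evoked("evoked_invalid",
                sprintf("unknown input role(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  structure(
    list(paths = paths, alpha = alpha, epoch_window = epoch_window,
         test_window = test_window, sigma = sigma, bands = bands, myo = myo,
         staging_window_s = staging_window_s, pre_post_s = pre_post_s,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads the configured inputs, then runs every stage whose inputs are
#' available: vigilance staging validation, the sleep-disturbance test,
#' per-site evoked-LFP analysis, per-unit spike analysis with cell
#' classification, and the myoelectric session analysis. Each output file
#' carries the seed and a hash of the configuration; exclusion counts are
#' reported in the bundle.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of stage results (also written as JSON
#'   and TSV files under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  if (is.null(p$events) || is.null(p$hypnogram)) {
    stop_evoked("evoked_invalid", "events and hypnogram inputs are required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash covers everything that affects the results (not the output path)
  meta <- list(seed = config$seed,
               config_hash = rlang::hash(config[setdiff(names(config),
                                                        "out_dir")]))
  events <- read_events(p$events)
  hyp <- read_hypnogram(p$hypnogram)
  bundle <- list(meta = meta)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_evoked("evoked_stage",
                  sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    bundle[[name]] <<- res
    res
  }
  if (!is.null(p$eeg)) {
    eeg <- read_recording(p$eeg, channel = "EEG")
    stage("staging", compare_states(eeg, hyp, config$bands,
                                    config$staging_window_s,
                                    alpha = config$alpha))
    stage("disturbance", glance(disturbance_test(
      eeg, events, hyp, config$bands, config$pre_post_s, state = "SWS",
      alpha = config$alpha)))
  }
  if (!is.null(p$lfp)) {
    lfp <- read_recording(p$lfp, channel = "LFP")
    res <- stage("lfp", lfp_site_analysis(lfp, events, hyp,
                                          config$epoch_window,
                                          config$test_window, config$alpha))
    bundle$lfp_table <- tidy(res)
  }
  if (!is.null(p$spikes)) {
    sp <- read_spikes(p$spikes)
    trains <- if (inherits(sp, "spike_train")) list(sp) else sp$train
    unit_rows <- purrr::map_dfr(trains, function(tr) {
      res <- spike_unit_analysis(tr, events, hyp, sigma = config$sigma)
      dplyr::mutate(res$category, unit_id = tr$unit_id[1], .before = 1)
    })
    stage("spikes", unit_rows)
    bundle$cell_table <- cell_report(unit_rows)
  }
  if (!is.null(p$gut)) {
    gut <- read_recording(p$gut, channel = "GUT")
    res <- stage("myo", myo_session(gut, events, config$myo, hyp,
                                    state = "SWS", alpha = config$alpha))
    bundle$myo_table <- glance(res)
  }
  # persist: JSON summary + TSV tables
  json_out <- purrr::map(bundle, function(x) {
    if (is.data.frame(x)) x
    else if (inherits(x, c("myo_session_result"))) glance(x)
    else if (inherits(x, "lfp_site_result")) tidy(x)
    else x
  })
  jsonlite::write_json(json_out, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in names(bundle)) {
    if (is.data.frame(bundle[[nm]])) {
      utils::write.table(bundle[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(bundle)
}

#' Write a complete synthetic session to disk
#'
#' Generates a coherent session (hypnogram, stimulus train, EEG, evoked
#' LFP, spike trains, gut signal) with known ground truth and writes the
#' delimited-text files of the interchange formats plus a `truth.json`
#' sidecar describing every injected response, for recovery tests.
#'
#' @param dir Output directory.
#' @param seed Base seed.
#' @param block_s WAKE/SWS block length in seconds.
#' @param lfp_rate,eeg_rate,gut_rate Sampling rates.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_experiment <- function(dir, seed = 1, block_s = 600,
                                lfp_rate = 500, eeg_rate = 200,
                                gut_rate = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hyp <- gen_hypnogram(c("WAKE", "SWS", "WAKE", "SWS"), rep(block_s, 4))
  ev <- gen_stim_times(hyp, c(45, 60), seed = child_seed(seed, 1))
  lfp_spec <- evoked_spec(0.12, 5, 0.25, "excitatory", "SWS")
  spike_specs <- evoked_spec(0.12, 4, 0.2, "excitatory", "SWS")
  gspec <- gut_spec(stim_gain = 1.5, burst_stim_gain = 2)
  eeg <- gen_eeg(hyp, rate = eeg_rate, seed = child_seed(seed, 2))
  lfp <- gen_lfp_evoked(hyp, ev, lfp_spec, rate = lfp_rate,
                        seed = child_seed(seed, 3))
  train <- gen_spikes(hyp, ev, baseline_hz = 15, specs = spike_specs,
                      seed = child_seed(seed, 4), unit_id = "u1")
  gut <- gen_gut(hyp, ev, gspec, rate = gut_rate,
                 seed = child_seed(seed, 5))
  paths <- list(
    hypnogram = file.path(dir, "hypnogram.tsv"),
    events = file.path(dir, "events.tsv"),
    eeg = file.path(dir, "eeg.tsv"),
    lfp = file.path(dir, "lfp.tsv"),
    spikes = file.path(dir, "spikes.tsv"),
    gut = file.path(dir, "gut.tsv"),
    truth = file.path(dir, "truth.json"))
  write_hypnogram(hyp, paths$hypnogram)
  write_events(ev, paths$events)
  write_recording(eeg, paths$eeg)
  write_recording(lfp, paths$lfp)
  write_spikes(train, paths$spikes)
  write_recording(gut, paths$gut)
  jsonlite::write_json(
    list(seed = seed,
         lfp = as.list(lfp_spec), spikes = as.list(spike_specs),
         gut = gspec[c("slow_wave_hz", "burst_rate_per_min", "stim_gain",
                       "stim_effect_s", "burst_stim_gain", "stim_state")]),
    paths$truth, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(paths)
}
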