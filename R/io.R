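# Readers and writers for the delimited-text interchange formats. All files
# are tab-separated with a header line; decimal point is '.', times are
# seconds. Formats:
#   recording: time_s \t value        (uniform sampling enforced)
#   events:    onset_s \t artifact \t label
#   spikes:    unit_id \t time_s
#   hypnogram: start_s \t end_s \t state

read_tsv_base <- function(path) {
  if (!file.exists(path)) {
    stop_evoked("evoked_io", sprintf("file not found: %s", path))
  }
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a continuous recording from delimited text
#'
#' Two tab-separated columns `time_s`, `value` with a header. Sampling must
#' be uniform: the rate is inferred from the median time step and every
#' timestamp must agree with the uniform grid within `tol` relative error —
#' non-uniform files are an error, never silently resampled.
#'
#' @param path File path.
#' @param channel Channel role tag for the resulting [cont_rec()].
#' @param format Input format; only `"delimited"` is currently supported.
#' @param tol Relative timestamp tolerance (default 1e-6).
#' @return A [cont_rec()].
#' @export
read_recording <- function(path, channel = "OTHER", format = "delimited",
                           tol = 1e-6) {
  format <- match.arg(format, "delimited")
  df <- read_tsv_base(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop_evoked("evoked_io", "recording file needs columns time_s, value")
  }
  t <- df$time_s
  if (length(t) < 2L) stop_evoked("evoked_io", "recording too short")
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop_evoked("evoked_io", sprintf("non-monotone time column at row %d",
                                     which(dt <= 0)[1] + 1L))
  }
  step <- median(dt)
  rate <- 1 / step
  grid <- t[1] + (seq_along(t) - 1L) * step
  bad <- which(abs(t - grid) > tol * max(abs(t), 1))
  if (length(bad)) {
    stop_evoked("evoked_io",
                sprintf("non-uniform sampling; first bad index %d", bad[1]))
  }
  cont_rec(df$value, rate = rate, start_time = t[1], channel = channel)
}

#' Write a continuous recording to delimited text
#' @param rec A [cont_rec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = sprintf("%.17g", rec_times(rec)),
                   value = sprintf("%.17g", rec$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write stimulus events
#' @param path File path (columns `onset_s`, `artifact` 0/1, `label`).
#' @return An [event_series()].
#' @export
read_events <- function(path) {
  df <- read_tsv_base(path)
  event_series(df$onset_s, artifact = as.logical(df$artifact),
               label = df$label)
}

#' @rdname read_events
#' @param events An [event_series()].
#' @export
write_events <- function(events, path) {
  df <- data.frame(onset_s = sprintf("%.17g", events$onset_s),
                   artifact = as.integer(events$artifact),
                   label = events$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write spike trains
#' @param path File path (columns `unit_id`, `time_s`).
#' @return A tibble with one [spike_train()] per unit, held in a list-column
#'   `train` keyed by `unit_id` (single-unit files return the train
#'   directly).
#' @export
read_spikes <- function(path) {
  df <- read_tsv_base(path)
  units <- split(df$time_s, df$unit_id)
  if (length(units) == 1L) {
    return(spike_train(units[[1]], unit_id = names(units)))
  }
  tibble(unit_id = names(units),
         train = purrr::map2(units, names(units),
                             ~ spike_train(.x, unit_id = .y)))
}

#' @rdname read_spikes
#' @param train A [spike_train()] (or bind-rows of several).
#' @export
write_spikes <- function(train, path) {
  df <- data.frame(unit_id = train$unit_id,
                   time_s = sprintf("%.17g", train$time_s))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a hypnogram
#' @param path File path (columns `start_s`, `end_s`, `state`).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  df <- read_tsv_base(path)
  hypnogram(df$start_s, df$end_s, df$state)
}

#' @rdname read_hypnogram
#' @param hyp A [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  df <- as.data.frame(hyp)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
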