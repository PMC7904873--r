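#' Frequency bands used for vigilance staging
#'
#' The canonical EEG bands for separating slow wave sleep from wakefulness:
#' delta (1-4 Hz) and sleep spindles (7-14 Hz), whose power rises in slow
#' wave sleep, and gamma (30-75 Hz), whose power is higher in wakefulness.
#'
#' @param delta,spindles,gamma Numeric `c(lo, hi)` band edges in Hz.
#' @return A tibble of class `band_set` with columns `band`, `lo_hz`, `hi_hz`.
#' @examples
#' band_set()
#' @export
band_set <- function(delta = c(1, 4), spindles = c(7, 14), gamma = c(30, 75)) {
  bands <- list(delta = delta, spindles = spindles, gamma = gamma)
  for (b in bands) {
    if (length(b) != 2L || b[2] <= b[1]) {
      stop_evoked("evoked_invalid_band", "each band needs lo < hi")
    }
  }
  out <- tibble(band = names(bands),
                lo_hz = vapply(bands, `[`, 0, 1L),
                hi_hz = vapply(bands, `[`, 0, 2L))
  class(out) <- c("band_set", class(out))
  out
}

#' Multitaper power spectral density
#'
#' Eigenvalue-weighted average of `K` Slepian-tapered periodograms
#' ([dpss_tapers()]), with density normalization such that the integral of
#' the one-sided PSD over `[0, rate/2]` equals the segment variance
#' (Parseval). The segment is demeaned before tapering.
#'
#' @param segment A [cont_rec()] of at least one second.
#' @param NW Time-bandwidth product (default 3).
#' @param K Taper count (default 5); requires `K <= 2 NW - 1`.
#' @param nfft FFT length; defaults to the next power of two at least twice
#'   the segment length.
#' @return An object of class `psd_estimate`: a list with `freq_hz` (grid up
#'   to Nyquist), `power` (density, units^2 per Hz), `K`, `NW`, `segment_s`,
#'   `rate`.
#' @examples
#' seg <- cont_rec(sin(2 * pi * 10 * seq(0, 10, by = 1 / 200)), 200)
#' psd <- multitaper_psd(seg)
#' psd$freq_hz[which.max(psd$power)]
#' @export
multitaper_psd <- function(segment, NW = 3, K = 5L, nfft = NULL) {
  stopifnot(inherits(segment, "cont_rec"))
  x <- segment$samples
  n <- length(x)
  if (n < segment$rate) {
    stop_evoked("evoked_too_short", "segment shorter than 1 s")
  }
  if (K > 2 * NW - 1) {
    stop_evoked("evoked_invalid_taper",
                sprintf("K = %d exceeds 2 NW - 1 = %g", K, 2 * NW - 1))
  }
  x <- x - mean(x)
  dp <- dpss_tapers(n, NW, K)
  nfft <- nfft %||% max(2L * stats::nextn(n, 2L), 1024L)
  tapered <- dp$tapers * x          # n x K, recycles x down columns
  padded <- matrix(0, nfft, K)
  padded[1:n, ] <- tapered
  Y <- stats::mvfft(padded)
  nf <- nfft %/% 2L + 1L
  Pk <- (Mod(Y[1:nf, , drop = FALSE])^2) / segment$rate
  w <- dp$eigen / sum(dp$eigen)
  pow <- as.numeric(Pk %*% w)
  # one-sided: double everything except DC (and Nyquist for even nfft)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nf] <- 1
  pow <- pow * dbl
  structure(
    list(freq_hz = (0:(nf - 1L)) * segment$rate / nfft, power = pow,
         K = K, NW = NW, segment_s = n / segment$rate, rate = segment$rate),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %g s segment @ %g Hz, K = %d tapers, NW = %g, df = %.3g Hz\n",
    x$segment_s, x$rate, x$K, x$NW, x$freq_hz[2] - x$freq_hz[1]))
  invisible(x)
}

#' @export
as_tibble.psd_estimate <- function(x, ...) {
  tibble(freq_hz = x$freq_hz, power = x$power)
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the spectral density over `[lo, hi]`, with linear
#' interpolation at the band edges.
#'
#' @param psd A [multitaper_psd()] estimate.
#' @param band Numeric `c(lo, hi)` in Hz; must overlap the frequency grid.
#' @return Scalar power (signal units squared).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  lo <- band[1]; hi <- band[2]
  fmax <- psd$freq_hz[length(psd$freq_hz)]
  if (hi <= lo || lo > fmax || hi < 0) {
    stop_evoked("evoked_invalid_band", "band does not overlap frequency grid")
  }
  lo <- max(lo, 0); hi <- min(hi, fmax)
  inner <- psd$freq_hz > lo & psd$freq_hz < hi
  fgrid <- c(lo, psd$freq_hz[inner], hi)
  pgrid <- approx(psd$freq_hz, psd$power, xout = fgrid, rule = 2)$y
  trapz(fgrid, pgrid)
}

# Band powers for every row of a band_set, for one segment.
segment_band_powers <- function(segment, bands, NW = 3, K = 5L) {
  psd <- multitaper_psd(segment, NW = NW, K = K)
  vapply(seq_len(nrow(bands)),
         function(i) band_power(psd, c(bands$lo_hz[i], bands$hi_hz[i])),
         numeric(1))
}

# Extract a [t0, t1) slice of a recording as a new recording.
rec_slice <- function(rec, t0, t1) {
  i0 <- time_to_index(t0, rec$start_time, rec$rate)
  i1 <- time_to_index(t1, rec$start_time, rec$rate) - 1L
  if (i0 < 1L || i1 > length(rec$samples) || i1 < i0) {
    stop_evoked("evoked_invalid_window", "slice outside recording")
  }
  cont_rec(rec$samples[i0:i1], rec$rate, start_time = t0,
           channel = rec$channel, label = rec$label)
}
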