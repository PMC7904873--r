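# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on class.
stop_evoked <- function(class, msg, ...) {
  rlang::abort(message = msg, class = c(class, "evokedstate_error"), ...)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Uniform trapezoidal integral of y over x (x need not be uniform).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Sample index of the time point `t` in a recording grid; 1-based.
# Sample k (1-based) sits at start_time + (k - 1) / rate.
time_to_index <- function(t, start_time, rate) {
  as.integer(round((t - start_time) * rate)) + 1L
}

# Moving-average smoothing with edge padding (window in samples, made odd).
# Cumsum-based, O(n) regardless of window width.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  pad <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  cs <- c(0, cumsum(xp))
  (cs[(width + 1L):(width + n)] - cs[1:n]) / width
}

# Analytic signal via the FFT construction; x must be a real vector.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Derive a reproducible child seed (kept below 2^31) from a base seed.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}
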