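# Independent brute-force oracles and tiny trace builders used across
# the suite. The oracles deliberately share no code with the package.

# Linear-interpolation percentile: sort and interpolate between order
# statistics at position (n - 1) * p + 1.
bf_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force Hampel pass: double loop, centered window, inclusive
# endpoints with the same 1e-9 tolerance the implementation documents.
bf_hampel <- function(t, x, window = 1.4, t_mult = 3, abs_cap = 1.5) {
  present <- which(!is.na(x))
  keep <- rep(FALSE, length(x))
  half <- window / 2 + 1e-9
  for (i in present) {
    w <- x[present[abs(t[present] - t[i]) <= half]]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    dev <- abs(x[i] - m)
    keep[i] <- dev <= abs_cap && (s <= 0 || dev <= t_mult * s)
  }
  keep
}

# A 13 s, 30 Hz trace with constant diameter (optionally overridden at
# chosen sample indices).
flat_trace <- function(value = 5, n = 390, rate = 30, overrides = NULL,
                       device_valid = TRUE, ...) {
  d <- rep(value, n)
  if (!is.null(overrides)) {
    d[as.integer(names(overrides))] <- unname(overrides)
  }
  pupil_trace((seq_len(n) - 1) / rate, d, device_valid = device_valid,
              sampling_rate = rate, ...)
}

# Indices of samples inside the 2-4 s post-onset window of a 30 Hz
# trace with onset at 3 s (t in [5, 7)).
window_idx <- function(trace, start = 2, end = 4) {
  onset <- trace$stimulus_onset_s[1]
  which(trace$t_s >= onset + start & trace$t_s < onset + end)
}
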