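# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# O(n^2) arousal-rule checker: a press is an arousal iff every earlier
# press is at least `min_gap` before it (and the run start is too).
oracle_detect <- function(presses, run_start, min_gap = 20) {
  presses <- sort(presses)
  is_arousal <- vapply(seq_along(presses), function(i) {
    earlier <- presses[presses < presses[i]]
    last <- if (length(earlier)) max(earlier) else run_start
    presses[i] - last >= min_gap
  }, logical(1L))
  out <- presses[is_arousal]
  # response counts: presses from this arousal up to the next arousal
  n_resp <- vapply(which(is_arousal), function(i) {
    later_arousals <- which(is_arousal & seq_along(presses) > i)
    end <- if (length(later_arousals)) min(later_arousals) - 1L else length(presses)
    end - i + 1L
  }, integer(1L))
  list(times = out, n_responses = n_resp)
}

# Exhaustive shift-and-correlate lag oracle (per-shift Pearson over the
# overlap), independent of the compiled implementation.
oracle_xcorr <- function(x, y, dt, max_lag) {
  K <- round(max_lag / dt)
  shifts <- -K:K
  r <- vapply(shifts, function(s) {
    n <- length(x)
    if (s >= 0) { xa <- x[(1 + s):n]; ya <- y[1:(n - s)] }
    else { xa <- x[1:(n + s)]; ya <- y[(1 - s):n] }
    if (length(xa) < 3 || sd(xa) == 0 || sd(ya) == 0) return(NA_real_)
    cor(xa, ya)
  }, numeric(1L))
  best <- which(r >= max(r, na.rm = TRUE) - 1e-12)
  best <- best[order(abs(shifts[best]), shifts[best])]
  list(lag = shifts[best[1L]] * dt, r = r[best[1L]], r_all = r)
}

# A smooth random series: low-pass filtered white noise.
smooth_noise <- function(n, cutoff = 10) {
  x <- rnorm(n)
  k <- dnorm(seq(-3, 3, length.out = cutoff))
  as.numeric(stats::filter(x, k / sum(k), sides = 2, method = "convolution")) ->
    y
  y[is.na(y)] <- 0
  y
}

# Simple phase unwrap for test assertions.
unwrap_phase_for_test <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# Direct FFT analytic-signal oracle (applied to raw in-band input, no
# filtering or resampling).
analytic_oracle <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  fft(X * h, inverse = TRUE) / n
}
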