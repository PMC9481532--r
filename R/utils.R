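# Internal numerical utilities shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a component tag,
# kept within 32-bit integer range.
child_seed <- function(seed, tag) {
  h <- 5381
  for (ch in utf8ToInt(as.character(tag)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629) + 1L
}

# Polynomial string hash as 8 hex digits; used for provenance blocks.
fnv1a_hex <- function(x) {
  h <- 5381
  for (ch in utf8ToInt(x))
    h <- (h * 33 + ch) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Analytic signal via the FFT half-spectrum construction
#'
#' Returns the complex analytic signal of a real series: the signal plus
#' i times its Hilbert transform. `Mod()` of the result is the instantaneous
#' amplitude envelope and `Arg()` the instantaneous phase.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("series too short for analytic signal", call. = FALSE)
  X <- fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Unwrap a phase series (radians).
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1L], p[1L] + cumsum(dp))
}

# Wrap phases to [0, 2*pi).
wrap_2pi <- function(p) p %% (2 * pi)

# Design a linear-phase (windowed-sinc, Hamming) FIR bandpass and apply it
# with zero phase by symmetric convolution; edges are handled by reflection
# padding. `transition` is the half-width of the transition band in Hz.
fir_bandpass <- function(x, fs, band, transition = NULL) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L])
    stop("`band` must be an increasing positive pair (Hz)", call. = FALSE)
  if (band[2L] >= fs / 2)
    stop("band edge at or above Nyquist (", fs / 2, " Hz)", call. = FALSE)
  if (is.null(transition)) transition <- max(0.25 * band[1L], 0.02)
  # Hamming-window FIR: transition width ~ 3.3 * fs / ntaps
  ntaps <- ceiling(3.3 * fs / transition)
  ntaps <- min(ntaps, floor((length(x) - 1L) / 2L) * 2L)
  if (ntaps %% 2L == 1L) ntaps <- ntaps + 1L  # even order -> odd length, type I
  b <- signal::fir1(ntaps, band / (fs / 2), type = "pass")
  b <- as.numeric(b)
  half <- (length(b) - 1L) / 2L
  xp <- c(rev(x[2L:(half + 1L)]), x, rev(x[(length(x) - half):(length(x) - 1L)]))
  y <- stats::filter(xp, b, method = "convolution", sides = 2L)
  as.numeric(y[(half + 1L):(half + length(x))])
}

# Linear interpolation onto a new time grid with constant extrapolation.
interp_hold <- function(t, v, tout) {
  approx(t, v, xout = tout, method = "linear", rule = 2)$y
}

# Two-sided one-sample / paired t-test that tolerates zero variance:
# a zero-variance, zero-mean difference gives t = 0, p = 1; a
# zero-variance nonzero difference gives p = 0.
t_onesample <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) return(list(t = NA_real_, p = NA_real_, n = n))
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, n = n))
    return(list(t = sign(m) * Inf, p = 0, n = n))
  }
  tval <- m / (s / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), df = n - 1L), n = n)
}

# Percentile bootstrap CI bounds.
pct_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- quantile(x, probs = c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(lo = q[1L], hi = q[2L])
}
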