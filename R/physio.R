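# Cardiac/respiratory phase estimation, sliding-window (dynamic) RETROICOR
# harmonic regression, and band-limited amplitude envelopes.

#' Cardiac phase from a pulse waveform
#'
#' The waveform is bandpass filtered (0.2-10 Hz), peaks are detected as
#' local maxima with a minimum inter-peak distance (default 0.4 s, the
#' shortest plausible interbeat interval), and the phase at time t between
#' consecutive peaks p_k and p_{k+1} is 2*pi*(t - p_k)/(p_{k+1} - p_k),
#' i.e. each interbeat interval is mapped linearly onto one cycle. The
#' phase is resampled onto the requested (BOLD) time grid; beyond the
#' first/last peak it is extrapolated at the adjacent interval's rate.
#'
#' @param waveform numeric cardiac/pulse waveform (a.u.).
#' @param fs sampling rate (Hz), >= 20 recommended.
#' @param bold_time numeric vector: time axis (s) to resample the phase on.
#' @param t0 time of the first waveform sample (s), default 0.
#' @param band bandpass edges (Hz), default `c(0.2, 10)` (upper clipped
#'   below Nyquist).
#' @param min_ipi minimum inter-peak interval (s), default 0.4.
#' @return list with `phase` (rad, wrapped to \[0, 2*pi)) and `time`
#'   (= `bold_time`).
#' @export
cardiac_phase <- function(waveform, fs, bold_time, t0 = 0,
                          band = c(0.2, 10), min_ipi = 0.4) {
  if (length(waveform) / fs < 10) stop("recording shorter than 10 s",
                                       call. = FALSE)
  band[2L] <- min(band[2L], 0.45 * fs)
  filt <- fir_bandpass(waveform, fs, band, transition = 0.1)
  # threshold well below the systolic peaks but above inter-beat ripple
  thr <- 0.5 * quantile(filt, 0.99, names = FALSE)
  pk <- pracma::findpeaks(filt, minpeakdistance = max(1L, round(min_ipi * fs)),
                          minpeakheight = max(thr, 0))
  if (is.null(pk) || nrow(pk) < 3L)
    stop("insufficient signal: fewer than 3 cardiac peaks detected",
         call. = FALSE)
  peak_t <- t0 + (sort(pk[, 2L]) - 1L) / fs
  # unwrapped phase: 2*pi*k at the k-th peak, linear between, linear beyond
  uw <- approx(peak_t, 2 * pi * (seq_along(peak_t) - 1L), xout = bold_time,
               method = "linear", rule = 1)$y
  before <- bold_time < peak_t[1L]
  after <- bold_time > peak_t[length(peak_t)]
  rate1 <- 2 * pi / diff(peak_t[1:2])
  rateN <- 2 * pi / diff(peak_t[length(peak_t) - 1:0])
  uw[before] <- (bold_time[before] - peak_t[1L]) * rate1
  uw[after] <- 2 * pi * (length(peak_t) - 1L) +
    (bold_time[after] - peak_t[length(peak_t)]) * rateN
  list(phase = wrap_2pi(uw), time = bold_time, peak_times = peak_t)
}

#' Respiratory phase from a respiration waveform
#'
#' FIR bandpass (default 0.16-0.4 Hz) followed by the angle of the analytic
#' signal (Hilbert transform), resampled to the requested grid. The phase
#' of a cosine at its maxima is 0.
#'
#' @inheritParams cardiac_phase
#' @param band bandpass edges (Hz), default `c(0.16, 0.4)`.
#' @return list with `phase` (rad, wrapped to \[0, 2*pi)) and `time`.
#' @export
respiratory_phase <- function(waveform, fs, bold_time, t0 = 0,
                              band = c(0.16, 0.4)) {
  if (length(waveform) / fs < 60) stop("recording shorter than 60 s",
                                       call. = FALSE)
  if (sd(waveform) == 0) stop("degenerate signal: constant input",
                              call. = FALSE)
  filt <- fir_bandpass(waveform, fs, band, transition = 0.05)
  ph <- unwrap_phase(Arg(analytic_signal(filt)))
  t_in <- t0 + (seq_along(waveform) - 1L) / fs
  out <- approx(t_in, ph, xout = bold_time, method = "linear", rule = 2)$y
  list(phase = wrap_2pi(out), time = bold_time)
}

#' Sliding-window harmonic regression of physiological noise
#'
#' Dynamic RETROICOR-style cleaning: within each sliding window (default
#' 1000 s, step 400 s) the series is regressed on sines and cosines of
#' integer multiples of the cardiac and respiratory phases (harmonics 1 and
#' 2 by default, eight regressors) plus an intercept and, optionally, a
#' linear drift term. The physiological betas are assigned to the window
#' centers, linearly interpolated to every sample, held constant beyond the
#' first/last center, and the reconstructed physiological component is
#' subtracted. Only the harmonic component is removed (the intercept/drift
#' terms protect the betas from trend leakage but are retained in the
#' output). A series shorter than one window falls back to a single
#' full-length window with a message.
#'
#' @param values BOLD series on a uniform grid.
#' @param dt sampling interval (s).
#' @param cardiac,resp phase series on the same grid (rad; e.g. from
#'   [cardiac_phase()] / [respiratory_phase()]).
#' @param window,step sliding-window length and step (s), defaults 1000/400.
#' @param harmonics integer vector of phase multiples, default `1:2`.
#' @param drift include a per-window linear drift regressor, default TRUE.
#' @return list with `values` (cleaned, same length), `physio` (removed
#'   component), `n_windows`.
#' @export
dynamic_retroicor <- function(values, dt, cardiac, resp, window = 1000,
                              step = 400, harmonics = 1:2, drift = TRUE) {
  n <- length(values)
  if (length(cardiac) != n || length(resp) != n)
    stop("phase series must match the BOLD grid", call. = FALSE)
  if (!length(harmonics)) stop("`harmonics` must be nonempty", call. = FALSE)
  if (step > window) stop("`step` must be <= `window`", call. = FALSE)
  X <- do.call(cbind, lapply(harmonics, function(k)
    cbind(sin(k * cardiac), cos(k * cardiac), sin(k * resp), cos(k * resp))))
  p <- ncol(X)
  t_axis <- (seq_len(n) - 1L) * dt
  w_samp <- round(window / dt)
  if (w_samp >= n) {
    message("series shorter than one window: using a single full-length fit")
    starts <- 1L
    w_samp <- n
  } else {
    starts <- seq(1L, n - w_samp + 1L, by = max(1L, round(step / dt)))
    if (tail(starts, 1L) < n - w_samp + 1L) starts <- c(starts, n - w_samp + 1L)
  }
  centers <- (starts - 1L + (w_samp - 1L) / 2) * dt
  betas <- matrix(NA_real_, nrow = length(starts), ncol = p)
  for (i in seq_along(starts)) {
    sel <- starts[i]:(starts[i] + w_samp - 1L)
    D <- cbind(1, if (drift) scale(t_axis[sel]), X[sel, , drop = FALSE])
    fit <- lm.fit(D, values[sel])
    betas[i, ] <- tail(coef(fit), p)
  }
  bt <- if (length(starts) == 1L) {
    matrix(betas[1L, ], nrow = n, ncol = p, byrow = TRUE)
  } else {
    apply(betas, 2L, function(b) interp_hold(centers, b, t_axis))
  }
  physio <- rowSums(bt * X)
  list(values = values - physio, physio = physio, n_windows = length(starts))
}

#' Band-limited instantaneous amplitude envelope
#'
#' Bandpass filters the series and takes the modulus of the analytic
#' signal. Used for respiratory (0.16-0.4 Hz) and pulse (0.7-1.8 Hz)
#' amplitude around arousal.
#'
#' @param values numeric series.
#' @param fs sampling rate (Hz).
#' @param band bandpass edges (Hz); must lie below Nyquist.
#' @return numeric envelope (non-negative, same length).
#' @export
amplitude_envelope <- function(values, fs, band) {
  if (band[2L] >= fs / 2)
    stop("band outside Nyquist range", call. = FALSE)
  if (all(values == 0)) return(numeric(length(values)))
  Mod(analytic_signal(fir_bandpass(values, fs, band)))
}
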