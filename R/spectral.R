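# Multitaper spectrograms and band-limited (alpha) power around arousal.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem.
#' Tapers are unit-energy and sign-normalized (first taper positive mean).
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product, default 2.
#' @param k number of tapers, default 3 (at most `2*nw - 1` are well
#'   concentrated).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  if (k > n) stop("more tapers than samples", call. = FALSE)
  W <- nw / n
  i <- seq_len(n) - 1L
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (seq_len(n - 1L)) * (n - seq_len(n - 1L)) / 2
  A <- diag(d)
  A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- e
  A[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- e
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  }
  V
}

#' Multitaper spectrogram
#'
#' Slepian-taper averaged periodograms in sliding windows (defaults:
#' window 2 s, step 1 s, 3 tapers with time-bandwidth product 2). Power is
#' one-sided density (a.u.^2/Hz); window times are the window centers.
#'
#' @param values numeric series.
#' @param fs sampling rate (Hz).
#' @param window,step window length and slide (s), defaults 2 and 1.
#' @param tapers number of tapers, default 3.
#' @param nw time-bandwidth product, default 2.
#' @param t0 time of the first sample (s), default 0.
#' @return object of class `spectrogram`: list with `times` (s), `freqs`
#'   (Hz), `power` (times x freqs matrix, >= 0).
#' @export
multitaper_spectrogram <- function(values, fs, window = 2, step = 1,
                                   tapers = 3, nw = 2, t0 = 0) {
  n <- length(values)
  nwin <- round(window * fs)
  if (nwin > n) stop("series shorter than one window", call. = FALSE)
  nstep <- max(1L, round(step * fs))
  V <- dpss_tapers(nwin, nw, tapers)
  nf <- nwin %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / nwin
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  power <- matrix(0, length(starts), nf)
  for (i in seq_along(starts)) {
    seg <- values[starts[i]:(starts[i] + nwin - 1L)]
    seg <- seg - mean(seg)
    sp <- numeric(nf)
    for (j in seq_len(tapers)) {
      F <- fft(seg * V[, j])[seq_len(nf)]
      sp <- sp + Mod(F)^2
    }
    sp <- sp / tapers / fs
    sp[c(-1L, -nf)] <- 2 * sp[c(-1L, -nf)]  # one-sided
    power[i, ] <- sp
  }
  structure(list(times = t0 + (starts - 1L) / fs + window / 2,
                 freqs = freqs, power = power),
            class = "spectrogram")
}

#' Mean power in a frequency band over time
#'
#' @param spec a `spectrogram`.
#' @param band frequency band (Hz pair), e.g. `c(8, 13)` for alpha.
#' @return list with `values` (mean band power per window) and `times`.
#' @export
band_power <- function(spec, band) {
  sel <- spec$freqs >= band[1L] & spec$freqs <= band[2L]
  if (!any(sel)) stop("empty band: no frequency bins inside", call. = FALSE)
  list(values = rowMeans(spec$power[, sel, drop = FALSE]),
       times = spec$times)
}

#' Paired pre/post test of band power around events
#'
#' Averages the power series in the `pre` seconds before and `post`
#' seconds after each event and compares the per-event means with a
#' two-sided paired t-test. Events without a full window on both sides are
#' dropped.
#'
#' @param values power series (e.g. from [band_power()]).
#' @param times its time axis (s).
#' @param event_times event (arousal) times (s).
#' @param pre,post window lengths (s), defaults 10/10.
#' @return list with `t`, `p`, `n`, and a data.frame `per_event` of pre and
#'   post means.
#' @export
prepost_test <- function(values, times, event_times, pre = 10, post = 10) {
  pe <- lapply(event_times, function(a) {
    s_pre <- times >= a - pre & times < a
    s_post <- times > a & times <= a + post
    if (!any(s_pre) || !any(s_post) ||
        a - pre < min(times) || a + post > max(times)) return(NULL)
    data.frame(event = a, pre = mean(values[s_pre]),
               post = mean(values[s_post]))
  })
  pe <- do.call(rbind, pe)
  if (is.null(pe) || nrow(pe) < 2L)
    stop("insufficient data: fewer than 2 events with complete windows",
         call. = FALSE)
  tt <- t_onesample(pe$post - pe$pre)
  list(t = tt$t, p = tt$p, n = nrow(pe), per_event = pe)
}
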