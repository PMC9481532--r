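# Synthetic session generator. Produces complete sessions (ROI BOLD,
# button-press logs, motion, cardiac/respiratory waveforms, optional
# EEG-like alpha trace, breathhold runs) with every later-estimated
# quantity recorded as ground truth.

THALAMIC_NUCLEI <- c("CM", "VPL", "VLP", "MD", "PUL", "LGN", "VA", "AV", "VLA")

# Frequency trajectory: slow sinusoidal drift kept inside a stated band.
.freq_traj <- function(t, lo, hi, period = 600, phase = 0) {
  mid <- (lo + hi) / 2
  amp <- 0.8 * (hi - lo) / 2
  mid + amp * sin(2 * pi * t / period + phase)
}

# Integrate an instantaneous-frequency vector into a phase (rad).
.freq_to_phase <- function(freq, dt) 2 * pi * cumsum(freq) * dt

# AR(1)-colored Gaussian noise with marginal standard deviation `sd`.
.ar1_noise <- function(n, sd, ar) {
  if (sd == 0) return(numeric(n))
  w <- rnorm(n, sd = if (ar != 0) sd * sqrt(1 - ar^2) else sd)
  if (ar == 0) return(w)
  as.numeric(stats::filter(w, ar, method = "recursive"))
}

# Schedule arousal times: unresponsive gaps of at least `min_quiet` seconds
# between the end of one response train and the next arousal.
.schedule_arousals <- function(duration, classes, breath_rate, min_quiet = 35,
                               max_quiet = 75, edge = 30) {
  times <- numeric(0)
  t <- edge + runif(1L, 0, max_quiet - min_quiet)
  press_int <- 1 / (2 * breath_rate)
  for (k in seq_along(classes)) {
    if (t + edge > duration - edge) break
    times <- c(times, t)
    n_press <- switch(classes[k],
                      sustained = 5L + stats::rpois(1L, 3),
                      transient = sample(1:2, 1L),
                      intermediate = sample(3:4, 1L))
    train <- (n_press - 1L) * press_int
    t <- t + train + runif(1L, min_quiet, max_quiet)
  }
  times
}

#' Generate a button-press log for a scheduled set of arousals
#'
#' Presses occur at roughly twice the breathing rate (one press per breath
#' in and per breath out) during responsive periods; each scheduled arousal
#' is preceded by at least 20 s of silence. Sustained arousals emit >= 5
#' presses, transient <= 2 (the triggering press counts as response #1).
#'
#' @param arousal_times scheduled arousal times (s), strictly increasing.
#' @param classes character vector (`sustained`/`transient`/`intermediate`),
#'   one per arousal.
#' @param breath_rate breathing rate (Hz), within 0.16-0.4.
#' @param run_end run duration (s).
#' @param seed RNG seed.
#' @param jitter fractional press-interval jitter, default 0.1.
#' @param n_presses optional integer vector overriding the per-class press
#'   counts.
#' @return data.frame with `onset`, `duration` (0), `trial_type` ("press").
#' @export
make_button_log <- function(arousal_times, classes, breath_rate = 0.25,
                            run_end, seed, jitter = 0.1, n_presses = NULL) {
  if (breath_rate < 0.16 || breath_rate > 0.4)
    stop("breath rate outside 0.16-0.4 Hz", call. = FALSE)
  stopifnot(length(classes) == length(arousal_times))
  if (is.unsorted(arousal_times, strictly = TRUE))
    stop("arousal times must be strictly increasing", call. = FALSE)
  press_int <- 1 / (2 * breath_rate)
  with_seed(seed, {
    presses <- numeric(0)
    for (k in seq_along(arousal_times)) {
      np <- if (!is.null(n_presses)) n_presses[k] else
        switch(classes[k],
               sustained = 5L + stats::rpois(1L, 3),
               transient = sample(1:2, 1L),
               intermediate = sample(3:4, 1L))
      iv <- press_int * (1 + runif(max(np - 1L, 0L), -jitter, jitter))
      train <- arousal_times[k] + c(0, cumsum(iv))
      if (length(presses) && train[1L] - max(presses) < 20)
        stop("invalid schedule: responsive periods overlap the 20 s rule",
             call. = FALSE)
      if (k < length(arousal_times) &&
          max(train) > arousal_times[k + 1L] - 20)
        stop("invalid schedule: response train runs into the next arousal's ",
             "quiescence", call. = FALSE)
      presses <- c(presses, train)
    }
    presses <- presses[presses <= run_end]
    data.frame(onset = presses, duration = 0, trial_type = "press",
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic cardiac and respiratory waveforms
#'
#' The cardiac channel is a pulse-like waveform (sharply peaked von
#' Mises-shaped cycle) whose instantaneous frequency follows the supplied
#' trajectory; the respiratory channel is a smooth oscillation following
#' its trajectory. Both carry additive Gaussian noise.
#'
#' @param cardiac_freq,resp_freq numeric vectors of instantaneous frequency
#'   (Hz) sampled at `fs`, or single constants; must stay within
#'   0.7-1.8 Hz (cardiac) and 0.16-0.4 Hz (respiratory).
#' @param fs sampling rate (Hz), >= 20.
#' @param duration recording length (s).
#' @param seed RNG seed.
#' @param noise_sd additive noise sd (a.u.), default 0.05.
#' @return list with `cardiac`, `resp` (waveforms), `fs`, `t0 = 0`,
#'   `cardiac_freq`, `resp_freq` (the trajectories used).
#' @export
make_physio <- function(cardiac_freq, resp_freq, fs, duration, seed,
                        noise_sd = 0.05) {
  if (fs < 20) stop("physio sampling rate must be >= 20 Hz", call. = FALSE)
  n <- round(duration * fs)
  if (length(cardiac_freq) == 1L) cardiac_freq <- rep(cardiac_freq, n)
  if (length(resp_freq) == 1L) resp_freq <- rep(resp_freq, n)
  if (any(cardiac_freq < 0.7 | cardiac_freq > 1.8))
    stop("cardiac trajectory outside 0.7-1.8 Hz", call. = FALSE)
  if (any(resp_freq < 0.16 | resp_freq > 0.4))
    stop("respiratory trajectory outside 0.16-0.4 Hz", call. = FALSE)
  ph_c <- .freq_to_phase(cardiac_freq, 1 / fs)
  ph_r <- .freq_to_phase(resp_freq, 1 / fs)
  with_seed(seed, {
    pulse <- exp(8 * (cos(ph_c) - 1))          # peaked once per cycle
    pulse <- (pulse - mean(pulse)) / sd(pulse)
    resp <- sin(ph_r)
    list(cardiac = pulse + rnorm(n, sd = noise_sd),
         resp = resp + rnorm(n, sd = noise_sd),
         fs = fs, t0 = 0,
         cardiac_freq = cardiac_freq, resp_freq = resp_freq)
  })
}

# Per-ROI arousal response component on the session grid.
.response_trace <- function(t, arousal_times, params) {
  out <- numeric(length(t))
  for (a in arousal_times) out <- out + hrf_curve(params, t - a)
  out
}

#' Generate a complete synthetic arousal session
#'
#' Builds a full session with recorded ground truth: per-ROI BOLD traces
#' (arousal responses with per-ROI lag and amplitude + slow drift +
#' amplitude-modulated cardiac/respiratory harmonics + AR(1) noise), a
#' button-press log, a motion trace with occasional spikes,
#' cardiac/respiratory waveforms, and optionally an EEG-like trace with an
#' alpha-band amplitude increase at each arousal.
#'
#' Thalamic-type ROIs activate before the arousal (response peak near the
#' arousal, shifted by the ROI's true lag); cortical-type ROIs carry a
#' slight early rise followed by a delayed deactivation.
#'
#' @param tr repetition time (s), e.g. 0.247.
#' @param duration session length (s), >= 300.
#' @param n_events number of scheduled arousals; `NULL` fills the session.
#' @param seed RNG seed (required; one global seed feeds per-component
#'   child seeds).
#' @param n_thalamic,n_cortical ROI counts, defaults 9 and 30.
#' @param lags named or plain numeric vector of true thalamic lags (s,
#'   relative to the whole-thalamus reference); default spans 2.1 s across
#'   the nine nuclei with CM/VPL leading and VA/AV/VLA lagging.
#' @param amplitude thalamic response amplitude (a.u.), scalar or per-ROI.
#' @param cort_amplitude cortical deactivation amplitude, default 1.
#' @param cort_delay delay of the cortical deactivation (s), default 5.
#' @param noise_sd marginal noise sd (a.u.); SNR = amplitude / noise_sd.
#' @param ar1 AR(1) coefficient of the noise, default 0.4 (0 = white).
#' @param physio_amp cardiac/respiratory contamination amplitude (a.u.),
#'   default 0.3; modulated +/-30% on a slow timescale (physiological
#'   artifact amplitude is non-stationary).
#' @param drift_amp amplitude of the slow baseline drift (a.u.), default 0.1.
#' @param sigma width (s) of the positive response Gaussian, default 2.
#' @param undershoot amplitude of a negative undershoot Gaussian (>= 0
#'   subtracted), default 0.
#' @param breath_rate behavioral breathing rate (Hz), default 0.25.
#' @param class_probs probabilities of sustained/transient/intermediate
#'   arousals, default c(0.46, 0.35, 0.19).
#' @param motion_spike_prob probability an arousal carries a motion spike
#'   (> 0.3 mm), default 0.
#' @param eeg generate an EEG-like channel (200 Hz) with arousal-locked
#'   alpha bursts, default FALSE.
#' @param arousal_times optional explicit arousal schedule (s).
#' @param classes optional explicit classes (with `arousal_times`).
#' @return an object of class `arousal_session`: list with `roi`
#'   (data.frame: `time` + one column per ROI), `tr`, `events` (press log),
#'   `motion` (6-column parameter matrix), `physio`, `eeg` (or NULL), and
#'   `truth` (ground truth, including per-component traces).
#' @export
make_session <- function(tr = 0.247, duration = 1800, n_events = NULL,
                         seed, n_thalamic = 9, n_cortical = 30,
                         lags = NULL, amplitude = 1, cort_amplitude = 1,
                         cort_delay = 5, noise_sd = 0.2, ar1 = 0.4,
                         physio_amp = 0.3, drift_amp = 0.1, sigma = 2,
                         undershoot = 0,
                         breath_rate = 0.25,
                         class_probs = c(0.46, 0.35, 0.19),
                         motion_spike_prob = 0, eeg = FALSE,
                         arousal_times = NULL, classes = NULL) {
  if (tr <= 0 || duration <= 0) stop("invalid config: TR and duration must be positive",
                                     call. = FALSE)
  if (duration < 300) stop("invalid config: duration must be >= 300 s", call. = FALSE)
  if (n_thalamic + n_cortical < 1) stop("invalid config: need >= 1 ROI", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  n <- round(duration / tr)
  t_axis <- (seq_len(n) - 1L) * tr
  if (!is.null(lags) && !is.null(names(lags)) && length(lags) == n_thalamic)
    thal_names <- names(lags)
  else thal_names <- if (n_thalamic <= length(THALAMIC_NUCLEI))
    THALAMIC_NUCLEI[seq_len(n_thalamic)] else
      c(THALAMIC_NUCLEI, paste0("thal", seq_len(n_thalamic - length(THALAMIC_NUCLEI))))
  cort_names <- if (n_cortical > 0) sprintf("ctx%02d", seq_len(n_cortical)) else character(0)
  if (is.null(lags)) {
    lags <- if (n_thalamic > 1)
      seq(-1.05, 1.05, length.out = n_thalamic) else 0
  }
  if (is.null(names(lags))) names(lags) <- thal_names
  amplitude <- rep_len(amplitude, n_thalamic)
  names(amplitude) <- thal_names

  # -- schedule & button log ------------------------------------------------
  cls_lvls <- c("sustained", "transient", "intermediate")
  if (is.null(arousal_times)) {
    sched <- with_seed(child_seed(seed, "schedule"), {
      k_max <- if (is.null(n_events)) ceiling(duration / 40) else n_events
      cl <- sample(cls_lvls, k_max, replace = TRUE, prob = class_probs)
      at <- .schedule_arousals(duration, cl, breath_rate)
      list(times = at, classes = cl[seq_along(at)])
    })
    arousal_times <- sched$times
    classes <- sched$classes
  } else if (is.null(classes)) {
    classes <- rep("sustained", length(arousal_times))
  }
  events <- make_button_log(arousal_times, classes, breath_rate,
                            run_end = duration,
                            seed = child_seed(seed, "presses"))

  # -- physiological recording & trajectories -------------------------------
  fs_physio <- 100
  t_phys <- (seq_len(round(duration * fs_physio)) - 1L) / fs_physio
  card_traj <- .freq_traj(t_phys, 0.9, 1.3, period = 500)
  resp_traj <- .freq_traj(t_phys, 0.2, 0.3, period = 380, phase = 1)
  physio <- make_physio(card_traj, resp_traj, fs_physio, duration,
                        seed = child_seed(seed, "physio"))
  # same trajectories on the BOLD grid (for contamination synthesis)
  card_f_bold <- .freq_traj(t_axis, 0.9, 1.3, period = 500)
  resp_f_bold <- .freq_traj(t_axis, 0.2, 0.3, period = 380, phase = 1)
  ph_c <- .freq_to_phase(card_f_bold, tr)
  ph_r <- .freq_to_phase(resp_f_bold, tr)

  # -- per-ROI traces -------------------------------------------------------
  roi_names <- c(thal_names, cort_names)
  n_roi <- length(roi_names)
  response <- drift <- physio_part <- noise <- matrix(0, n, n_roi,
                                                      dimnames = list(NULL, roi_names))
  hrf_list <- vector("list", n_roi)
  names(hrf_list) <- roi_names
  for (j in seq_len(n_roi)) {
    nm <- roi_names[j]
    s_roi <- child_seed(seed, paste0("roi:", nm))
    if (j <= n_thalamic) {
      pars <- hrf_params(a1 = amplitude[nm], mu1 = lags[nm], sigma1 = sigma,
                         a2 = -undershoot * amplitude[nm],
                         mu2 = lags[nm] + 6, sigma2 = 3)
    } else {
      # cortex: slight early rise then delayed deactivation
      pars <- hrf_params(a1 = 0.2 * cort_amplitude, mu1 = -2, sigma1 = 2,
                         a2 = -cort_amplitude, mu2 = cort_delay + 2,
                         sigma2 = 3)
    }
    hrf_list[[nm]] <- pars
    response[, j] <- .response_trace(t_axis, arousal_times, pars)
    roi_bits <- with_seed(s_roi, {
      ph0 <- runif(3L, 0, 2 * pi)
      camp <- physio_amp * runif(1L, 0.7, 1.3)
      ramp <- 0.7 * physio_amp * runif(1L, 0.7, 1.3)
      # slow amplitude drift (scan-long timescale, ~20+ min period)
      mod_c <- 1 + 0.3 * sin(2 * pi * t_axis / 1300 + ph0[1L])
      mod_r <- 1 + 0.3 * sin(2 * pi * t_axis / 1600 + ph0[2L])
      list(drift = drift_amp * (sin(2 * pi * t_axis / 600 + ph0[3L]) +
             0.5 * sin(2 * pi * t_axis / 210 + ph0[1L])),
           physio = camp * mod_c * (sin(ph_c) + 0.3 * sin(2 * ph_c)) +
             ramp * mod_r * (sin(ph_r) + 0.3 * sin(2 * ph_r)),
           noise = .ar1_noise(n, noise_sd, ar1))
    })
    drift[, j] <- roi_bits$drift
    physio_part[, j] <- roi_bits$physio
    noise[, j] <- roi_bits$noise
  }
  roi_mat <- response + drift + physio_part + noise
  roi <- data.frame(time = t_axis, roi_mat, check.names = FALSE)

  # -- motion ---------------------------------------------------------------
  motion <- with_seed(child_seed(seed, "motion"), {
    mp <- matrix(rnorm(n * 6L, sd = c(rep(0.004, 3), rep(8e-5, 3))),
                 n, 6L, byrow = TRUE)
    mp <- apply(mp, 2L, cumsum) * 0.02  # slow wander
    jit <- matrix(rnorm(n * 6L, sd = c(rep(0.002, 3), rep(4e-5, 3))),
                  n, 6L, byrow = TRUE)
    mp <- mp + jit
    spike_at <- arousal_times[runif(length(arousal_times)) < motion_spike_prob]
    extra <- t_axis[runif(n) < 3 / n]  # a few spikes away from events
    for (ts in c(spike_at, extra)) {
      i <- round(ts / tr) + 1L
      if (i >= 1L && i <= n) mp[i, 1L] <- mp[i, 1L] + 0.5
    }
    mp
  })

  # -- EEG-like alpha channel ----------------------------------------------
  eeg_out <- NULL
  if (isTRUE(eeg)) {
    eeg_out <- with_seed(child_seed(seed, "eeg"), {
      fs_eeg <- 200
      te <- (seq_len(round(duration * fs_eeg)) - 1L) / fs_eeg
      alpha_amp <- rep(0.3, length(te))
      for (a in arousal_times) {
        sel <- te >= a & te <= a + 10
        alpha_amp[sel] <- 1
      }
      sig <- alpha_amp * sin(2 * pi * 10 * te + runif(1L, 0, 2 * pi)) +
        rnorm(length(te), sd = 0.5)
      list(values = sig, fs = fs_eeg, t0 = 0, alpha_amp = alpha_amp)
    })
  }

  truth <- list(lags = lags, amplitudes = amplitude, hrf = hrf_list,
                arousal_times = arousal_times, classes = classes,
                cardiac_freq = card_f_bold, resp_freq = resp_f_bold,
                noise_sd = noise_sd, ar1 = ar1, seed = seed,
                components = list(response = response, drift = drift,
                                  physio = physio_part, noise = noise),
                clean = response + drift)
  structure(list(roi = roi, tr = tr, duration = duration, events = events,
                 motion = motion, physio = physio, eeg = eeg_out,
                 truth = truth),
            class = "arousal_session")
}

#' Generate a synthetic breathhold (cerebrovascular reactivity) session
#'
#' Each cycle is free breathing (27 s), three paced breaths (3 s in, 3 s
#' out; 18 s), and a breathhold (15 s); the release at the end of the hold
#' is logged as an event, and every ROI shows a post-release BOLD increase
#' delayed by its configured vascular delay.
#'
#' @param tr repetition time (s).
#' @param n_cycles number of task cycles, default 8.
#' @param free,paced,hold phase durations (s), defaults 27/18/15.
#' @param delays named numeric vector of per-ROI vascular delays (s).
#' @param amplitude post-release response amplitude, scalar or per-ROI
#'   (0 gives a flat, degenerate trace).
#' @param noise_sd marginal noise sd, default 0.1.
#' @param seed RNG seed.
#' @return an `arousal_session`-like list with `roi`, `tr`, `events`
#'   (trial_type "breathhold_release"), and `truth` (`delays`,
#'   `release_times`).
#' @export
make_breathhold_session <- function(tr = 0.247, n_cycles = 8, free = 27,
                                    paced = 18, hold = 15, delays,
                                    amplitude = 1, noise_sd = 0.1, seed) {
  if (n_cycles < 1) stop("invalid config: n_cycles must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(names(delays))) names(delays) <- paste0("roi", seq_along(delays))
  cycle <- free + paced + hold
  duration <- n_cycles * cycle + 40
  n <- round(duration / tr)
  t_axis <- (seq_len(n) - 1L) * tr
  release_times <- (seq_len(n_cycles) - 1L) * cycle + free + paced + hold
  amplitude <- rep_len(amplitude, length(delays))
  names(amplitude) <- names(delays)
  roi_mat <- with_seed(seed, {
    sapply(names(delays), function(nm) {
      pars <- hrf_params(a1 = amplitude[nm], mu1 = delays[nm] + 6, sigma1 = 3)
      .response_trace(t_axis, release_times, pars) +
        .ar1_noise(n, noise_sd, 0.4)
    })
  })
  roi <- data.frame(time = t_axis, roi_mat, check.names = FALSE)
  events <- data.frame(onset = release_times, duration = 0,
                       trial_type = "breathhold_release",
                       stringsAsFactors = FALSE)
  structure(list(roi = roi, tr = tr, duration = duration, events = events,
                 motion = NULL, physio = NULL, eeg = NULL,
                 truth = list(delays = delays, amplitudes = amplitude,
                              release_times = release_times, seed = seed)),
            class = "arousal_session")
}

#' @export
print.arousal_session <- function(x, ...) {
  cat("<arousal_session>\n")
  cat("  TR:", x$tr, "s; duration:", x$duration, "s;",
      ncol(x$roi) - 1L, "ROIs\n")
  cat("  events:", nrow(x$events), x$events$trial_type[1L], "\n")
  if (!is.null(x$truth$arousal_times))
    cat("  arousals:", length(x$truth$arousal_times),
        sprintf("(%s)", paste(table(x$truth$classes), collapse = "/")), "\n")
  invisible(x)
}
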