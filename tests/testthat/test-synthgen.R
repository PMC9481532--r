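test_that("sessions are bit-identical for identical config and seed", {
  a <- make_session(tr = 0.5, duration = 400, seed = 9, n_thalamic = 3,
                    n_cortical = 2)
  b <- make_session(tr = 0.5, duration = 400, seed = 9, n_thalamic = 3,
                    n_cortical = 2)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- make_session(tr = 0.5, duration = 400, seed = 10, n_thalamic = 3,
                     n_cortical = 2)
  expect_false(identical(a$roi, c2$roi))
})

test_that("noiseless single-ROI response peaks at arousal + HRF peak", {
  s <- make_session(tr = 0.25, duration = 400, seed = 1, n_thalamic = 1,
                    n_cortical = 0, lags = 0, noise_sd = 0, ar1 = 0,
                    physio_amp = 0, drift_amp = 0,
                    arousal_times = 150, classes = "sustained")
  tr_vals <- s$roi[[2]]
  t_ax <- s$roi$time
  # kernel mu = lag = 0 -> trace maximum at the sample nearest 150 s
  expect_equal(t_ax[which.max(tr_vals)], t_ax[which.min(abs(t_ax - 150))])
})

test_that("configured lags are recoverable downstream from noiseless ROIs", {
  s <- make_session(tr = 0.25, duration = 500, seed = 7, n_thalamic = 2,
                    n_cortical = 0, lags = c(A = 0, B = 0.5), noise_sd = 0,
                    ar1 = 0, physio_amp = 0, drift_amp = 0,
                    arousal_times = c(120, 250, 380),
                    classes = rep("sustained", 3))
  up <- lapply(c("A", "B"), function(nm)
    upsample_series(s$roi[[nm]], s$tr, 4))
  got <- xcorr_lag(up[[2]]$values, up[[1]]$values, up[[1]]$dt, max_lag = 5)
  expect_lt(abs(got$lag - 0.5), up[[1]]$dt + 1e-9)
})

test_that("button logs respect class press counts and the 20 s rule", {
  log1 <- make_button_log(100, "transient", run_end = 300, seed = 2,
                          n_presses = 1)
  expect_equal(log1$onset, 100)

  # empty schedule -> no arousals downstream
  expect_equal(nrow(detect_arousals(seq(1, 299, by = 3), 0, 300)), 0)

  set.seed(3)
  classes <- sample(c("sustained", "transient", "intermediate"), 10, TRUE)
  times <- 60 + 65 * (0:9)
  log10 <- make_button_log(times, classes, run_end = 800, seed = 3)
  ev <- detect_arousals(log10$onset, 0, 800)
  expect_equal(nrow(ev), 10)
  expect_equal(ev$class, classes)

  expect_error(make_button_log(c(100, 110), c("sustained", "sustained"),
                               run_end = 300, seed = 1),
               "invalid schedule")
  expect_error(make_button_log(100, "sustained", breath_rate = 0.5,
                               run_end = 300, seed = 1), "breath rate")
})

test_that("physio waveforms track their frequency trajectories", {
  p <- make_physio(1.0, 0.25, fs = 50, duration = 120, seed = 4,
                   noise_sd = 0)
  # constant 1 Hz cardiac: detected interpeak intervals = 1.0 s
  ph <- cardiac_phase(p$cardiac, p$fs, bold_time = seq(5, 115, by = 0.25))
  ipi <- diff(ph$peak_times)
  expect_true(all(abs(ipi - 1.0) <= 1 / p$fs + 1e-9))
  # constant 0.25 Hz respiration: analytic phase advances 2*pi per 4 s
  rp <- respiratory_phase(p$resp, p$fs, bold_time = seq(20, 100, by = 0.1))
  adv <- (rp$phase[121] - rp$phase[101]) %% (2 * pi)  # 2 s = half a cycle
  expect_lt(abs(adv - pi), 0.15)

  expect_error(make_physio(2.5, 0.25, 50, 60, 1), "cardiac trajectory")
  expect_error(make_physio(1, 0.5, 50, 60, 1), "respiratory trajectory")
})

test_that("noiseless contamination places spectral peaks at the fundamentals", {
  # constant-frequency contamination synthesized the same way the session
  # generator does it: harmonics of the integrated phase
  tr <- 0.2
  t <- seq(0, 600, by = tr)
  f_c <- 1.1; f_r <- 0.25
  x <- sin(2 * pi * f_c * t) + 0.3 * sin(2 * pi * 2 * f_c * t) +
    0.7 * (sin(2 * pi * f_r * t) + 0.3 * sin(2 * pi * 2 * f_r * t))
  sp <- stats::spec.pgram(stats::ts(x, deltat = tr), plot = FALSE, taper = 0)
  peaks <- sp$freq[pracma::findpeaks(sp$spec, npeaks = 6,
                                     sortstr = TRUE)[, 2]]
  for (f0 in c(f_c, 2 * f_c, f_r, 2 * f_r))
    expect_lt(min(abs(peaks - f0)), 0.02)
})

test_that("ground truth stores every later-estimated quantity", {
  s <- make_session(tr = 0.5, duration = 400, seed = 5, n_thalamic = 3,
                    n_cortical = 2)
  expect_named(s$truth$lags)
  expect_true(all(c("lags", "amplitudes", "hrf", "arousal_times", "classes",
                    "cardiac_freq", "resp_freq", "noise_sd", "seed",
                    "components", "clean") %in% names(s$truth)))
  expect_true(is.unsorted(s$truth$arousal_times) == FALSE)
  expect_true(all(diff(s$truth$arousal_times) > 20))
  expect_true(all(s$truth$cardiac_freq >= 0.7 & s$truth$cardiac_freq <= 1.8))
  expect_true(all(s$truth$resp_freq >= 0.16 & s$truth$resp_freq <= 0.4))
  # components sum to the emitted traces
  comp <- s$truth$components
  expect_equal(unname(as.matrix(s$roi[-1])),
               unname(comp$response + comp$drift + comp$physio + comp$noise))
})

test_that("breathhold sessions log one release per cycle with set delays", {
  bh <- make_breathhold_session(tr = 0.25, n_cycles = 8,
                                delays = c(A = 0, B = 0.3),
                                noise_sd = 0, seed = 6)
  expect_equal(nrow(bh$events), 8)
  expect_equal(diff(bh$events$onset), rep(60, 7))

  up <- lapply(c("A", "B"), function(nm)
    upsample_series(bh$roi[[nm]], bh$tr, 4))
  lag <- xcorr_lag(up[[2]]$values, up[[1]]$values, up[[1]]$dt, max_lag = 5)
  expect_lt(abs(lag$lag - 0.3), up[[1]]$dt + 1e-9)

  flat <- make_breathhold_session(tr = 0.25, n_cycles = 2,
                                  delays = c(A = 0), amplitude = 0,
                                  noise_sd = 0, seed = 6)
  expect_error(xcorr_lag(flat$roi$A, flat$roi$A, 0.25), "degenerate")
})

test_that("invalid generator configs are rejected", {
  expect_error(make_session(tr = -1, duration = 500, seed = 1), "positive")
  expect_error(make_session(tr = 0.5, duration = 100, seed = 1), ">= 300")
  expect_error(make_breathhold_session(n_cycles = 0, delays = c(A = 0),
                                       seed = 1), "n_cycles")
})
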