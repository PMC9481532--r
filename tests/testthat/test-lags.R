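test_that("cross-correlation lag recovers constructed shifts", {
  dt <- 0.1
  t <- seq(0, 60, by = dt)
  bump <- exp(-(t - 30)^2 / 8)
  self <- xcorr_lag(bump, bump, dt)
  expect_equal(self$lag, 0)
  expect_equal(self$r, 1, tolerance = 1e-12)
  shifted <- exp(-(t - 30.5)^2 / 8)  # same bump, 0.5 s later
  got <- xcorr_lag(shifted, bump, dt, max_lag = 5)
  expect_lt(abs(got$lag - 0.5), dt + 1e-9)
  expect_gt(got$r, 0.99)
})

test_that("lag estimator equals the exhaustive shift-and-correlate oracle", {
  set.seed(10)
  dt <- 0.25
  for (rep in 1:25) {
    x <- smooth_noise(300)
    y <- smooth_noise(300)
    got <- xcorr_lag(x, y, dt, max_lag = 8)
    want <- oracle_xcorr(x, y, dt, max_lag = 8)
    expect_equal(got$lag, want$lag)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$r_all, want$r_all, tolerance = 1e-10)
  }
})

test_that("lag is antisymmetric on smooth unimodal signals", {
  dt <- 0.1
  t <- seq(0, 80, by = dt)
  a <- exp(-(t - 40)^2 / 10)
  b <- exp(-(t - 41.3)^2 / 10)
  ab <- xcorr_lag(a, b, dt, max_lag = 6)$lag
  ba <- xcorr_lag(b, a, dt, max_lag = 6)$lag
  expect_lt(abs(ab + ba), dt + 1e-9)
})

test_that("degenerate and no-positive-peak inputs raise errors", {
  dt <- 0.25
  expect_error(xcorr_lag(rep(1, 100), rep(1, 100), dt), "degenerate")
  t <- seq(0, 25, by = dt)
  x <- sin(2 * pi * t / 50)
  expect_error(xcorr_lag(x, -x, dt, max_lag = 2, positive_only = TRUE),
               "no positive")
})

test_that("event bootstrap of lags is deterministic with honest CIs", {
  dt <- 0.25
  t <- seq(-10, 20, by = dt)
  mk_ens <- function(lag_s, n_ev, noise = 0) {
    row <- hrf_curve(hrf_params(a1 = 1, mu1 = lag_s, sigma1 = 2), t)
    mat <- matrix(rep(row, n_ev), nrow = n_ev, byrow = TRUE)
    if (noise > 0) mat <- mat + matrix(rnorm(length(mat), sd = noise),
                                       nrow = n_ev)
    structure(list(mat = mat, rel_time = t, dt = dt),
              class = "locked_ensemble")
  }
  ident <- list(A = mk_ens(-0.5, 6), B = mk_ens(0.5, 6))
  res <- bootstrap_lags(ident, n = 40, seed = 3)
  expect_equal(res$ci_lo, res$ci_hi)  # identical rows -> zero-width CIs
  set.seed(12)
  noisy <- list(A = mk_ens(-0.5, 12, 0.3), B = mk_ens(0.5, 12, 0.3))
  r1 <- bootstrap_lags(noisy, n = 60, seed = 5)
  r2 <- bootstrap_lags(noisy, n = 60, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$ci_lo <= r1$ci_hi))
})

test_that("hierarchical bootstrap widens CIs under between-subject jitter", {
  dt <- 0.1
  t <- seq(-10, 20, by = dt)
  set.seed(13)
  # per-subject scaling of the A-B separation: the subject effect must
  # differ between regions (a common shift cancels against the reference)
  mk_subj <- function(sep_scale, n_ev) {
    lapply(c(A = -0.4, B = 0.4), function(l) {
      row <- hrf_curve(hrf_params(a1 = 1, mu1 = l * sep_scale, sigma1 = 2), t)
      mat <- matrix(rep(row, n_ev), nrow = n_ev, byrow = TRUE) +
        matrix(rnorm(n_ev * length(t), sd = 0.2), nrow = n_ev)
      structure(list(mat = mat, rel_time = t, dt = dt),
                class = "locked_ensemble")
    })
  }
  subj <- lapply(exp(rnorm(5, sd = 0.6)), mk_subj, n_ev = 8)
  hier <- hierarchical_bootstrap_lags(subj, n = 120, seed = 4)
  hier2 <- hierarchical_bootstrap_lags(subj, n = 120, seed = 4)
  expect_identical(hier, hier2)
  pooled <- lapply(c("A", "B"), function(r) {
    mat <- do.call(rbind, lapply(subj, function(s) s[[r]]$mat))
    structure(list(mat = mat, rel_time = t, dt = dt),
              class = "locked_ensemble")
  })
  names(pooled) <- c("A", "B")
  flat <- bootstrap_lags(pooled, n = 120, seed = 4)
  expect_gt(mean(hier$ci_hi - hier$ci_lo), mean(flat$ci_hi - flat$ci_lo))
  expect_warning(hierarchical_bootstrap_lags(subj[1], n = 20, seed = 1),
                 "single subject")
})

test_that("sequence summary orders regions and reports the range", {
  tab <- data.frame(roi = c("x", "y", "z"), lag = c(0, -1, 1.1))
  s <- lag_sequence(tab)
  expect_equal(s$order, c("y", "x", "z"))
  expect_equal(s$range, 2.1)
  expect_equal(lag_sequence(data.frame(roi = c("a", "b"),
                                       lag = c(0.3, 0.3)))$range, 0)
})

test_that("breathhold lags recover configured vascular delays", {
  bh <- make_breathhold_session(tr = 0.25, n_cycles = 6,
                                delays = c(A = 0, B = 0.3), noise_sd = 0,
                                seed = 14)
  up <- lapply(bh$roi[c("A", "B")], function(v)
    upsample_series(v, bh$tr, 4))
  lags <- breathhold_lags(lapply(up, `[[`, "values"), up$A$dt,
                          bh$events$onset, n = 0)
  expect_lt(abs((lags$lag[match("B", lags$roi)] -
                   lags$lag[match("A", lags$roi)]) - 0.3), up$A$dt + 1e-9)
  # identical ROIs -> all lags 0
  same <- breathhold_lags(list(A = up$A$values, B = up$A$values), up$A$dt,
                          bh$events$onset, n = 0)
  expect_equal(same$lag, c(0, 0))
})

test_that("vascular correction subtracts breathhold lags per region", {
  ar <- data.frame(roi = c("A", "B"), lag = c(1.0, -0.5))
  bh <- data.frame(roi = c("B", "A"), lag = c(-0.45, 0.99))
  cor1 <- hemodynamic_correct(ar, bh)
  expect_equal(cor1$lag, c(1.0 - 0.99, -0.5 + 0.45))
  zero <- data.frame(roi = c("A", "B"), lag = c(0, 0))
  expect_equal(hemodynamic_correct(ar, zero)$lag, ar$lag)
  expect_error(hemodynamic_correct(ar, data.frame(roi = "C", lag = 1)),
               "region sets differ")
})

test_that("correction cancels purely vascular sequences end-to-end", {
  # same neural timing everywhere; only vascular delay differs
  delays <- c(A = 0, B = 0.4, C = 0.8)
  bh <- make_breathhold_session(tr = 0.25, n_cycles = 6, delays = delays,
                                noise_sd = 0.02, seed = 15)
  up <- lapply(bh$roi[names(delays)], function(v)
    upsample_series(v, bh$tr, 4))
  dt_up <- up$A$dt
  bh_lags <- breathhold_lags(lapply(up, `[[`, "values"), dt_up,
                             bh$events$onset, n = 0)
  # arousal session where true neural lags are 0 but traces carry the same
  # vascular delays
  s <- make_session(tr = 0.25, duration = 700, seed = 16, n_thalamic = 3,
                    n_cortical = 0, lags = delays, noise_sd = 0.02, ar1 = 0,
                    physio_amp = 0, drift_amp = 0)
  ar_det <- detect_arousals(s$events$onset, 0, 700)
  ens <- lapply(names(delays), function(nm) {
    u <- upsample_series(s$roi[[nm]], s$tr, 4)
    baseline_center(extract_windows(u$values, u$dt, ar_det$time))
  })
  names(ens) <- names(delays)
  ar_lags <- bootstrap_lags(ens, n = 0 + 30, seed = 2)
  corrected <- hemodynamic_correct(ar_lags, bh_lags)
  expect_lt(max(abs(corrected$lag)), 2 * dt_up + 1e-9)
})
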