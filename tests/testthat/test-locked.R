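test_that("upsampling interpolates linearly and preserves the original grid", {
  id <- upsample_series(c(1, 3, 2), dt = 1, factor = 1)
  expect_equal(id$values, c(1, 3, 2))
  up <- upsample_series(c(0, 4), dt = 1, factor = 4)
  expect_equal(up$values, 0:4)
  expect_equal(up$dt, 0.25)
  set.seed(2)
  x <- rnorm(50)
  up <- upsample_series(x, dt = 0.247, factor = 4)
  expect_identical(up$values[seq(1, length(up$values), by = 4)], x)
  # upsample then read back the original grid = identity
  expect_error(upsample_series(x, 1, factor = 0), "positive integer")
})

test_that("window extraction aligns rows at the nearest sample", {
  dt <- 0.25
  n <- 400
  vals <- seq_len(n)  # value encodes sample index
  # event exactly on a grid sample
  ens <- extract_windows(vals, dt, event_times = 50, pre = 10, post = 20)
  i0 <- 50 / dt + 1
  expect_equal(ens$mat[1, ], vals[(i0 - 40):(i0 + 80)])
  expect_true(0 %in% ens$rel_time)
  # off-grid event snaps to the nearest sample (<= dt/2 offset)
  ens2 <- extract_windows(vals, dt, event_times = 50.1, pre = 10, post = 20)
  expect_equal(ens2$mat[1, ], vals[(i0 - 40):(i0 + 80)])
  # boundary-crossing events are dropped with a message
  expect_message(
    ens3 <- extract_windows(vals, dt, event_times = c(5, 50), pre = 10,
                            post = 20), "dropped")
  expect_equal(nrow(ens3$mat), 1)
  expect_error(
    suppressMessages(extract_windows(vals, dt, event_times = 5, pre = 10,
                                     post = 20)),
    "empty ensemble")
  # excluded events are omitted
  ens4 <- extract_windows(vals, dt, event_times = c(50, 60),
                          excluded = c(FALSE, TRUE), pre = 10, post = 20)
  expect_equal(nrow(ens4$mat), 1)
})

test_that("ensemble mean peak recovers the generated response peak", {
  s <- make_session(tr = 0.25, duration = 600, seed = 3, n_thalamic = 1,
                    n_cortical = 0, lags = 0, noise_sd = 0, ar1 = 0,
                    physio_amp = 0, drift_amp = 0,
                    arousal_times = c(150, 300, 450),
                    classes = rep("sustained", 3))
  up <- upsample_series(s$roi[[2]], s$tr, 4)
  ens <- extract_windows(up$values, up$dt, s$truth$arousal_times)
  m <- ensemble_mean_sem(ens)
  # kernel peak is at lag 0 relative to arousal
  expect_lt(abs(m$rel_time[which.max(m$mean)]), up$dt + 1e-9)
})

test_that("baseline centering zeroes the early window and is idempotent", {
  dt <- 0.5
  ens <- extract_windows(rep(5, 200), dt, event_times = c(30, 40),
                         pre = 10, post = 20)
  c1 <- baseline_center(ens)
  expect_equal(max(abs(c1$mat)), 0)
  set.seed(4)
  ens$mat <- matrix(rnorm(2 * ncol(ens$mat)), nrow = 2)
  c1 <- baseline_center(ens)
  sel <- c1$rel_time >= -10 & c1$rel_time <= -7
  expect_lt(max(abs(rowMeans(c1$mat[, sel]))), 1e-10)
  c2 <- baseline_center(c1)
  expect_equal(c1$mat, c2$mat)
})

test_that("mean and SEM match direct per-column computation", {
  dt <- 1
  ens <- structure(list(mat = rbind(rep(0, 31), rep(2, 31)),
                        rel_time = -10:20, dt = dt), class = "locked_ensemble")
  m <- ensemble_mean_sem(ens)
  expect_equal(unique(m$mean), 1)
  expect_equal(unique(m$sem), 1)  # sd({0,2}) = sqrt(2), / sqrt(2) = 1
  ens$mat <- rbind(1:31, 1:31, 1:31)
  expect_equal(unique(ensemble_mean_sem(ens)$sem), 0)
  set.seed(5)
  ens$mat <- matrix(rnorm(10 * 31), 10)
  m <- ensemble_mean_sem(ens)
  expect_equal(m$mean, colMeans(ens$mat))
  expect_equal(m$sem, apply(ens$mat, 2, sd) / sqrt(10))
})

test_that("20% latency matches closed-form crossings", {
  # ramp 0 at t=0 to 1 at t=10: baseline 0, max 1, 20% crossing at 2 s
  t <- seq(-10, 20, by = 0.01)
  ramp <- ifelse(t < 0, 0, pmin(t / 10, 1))
  expect_equal(latency20(ramp, t), 2, tolerance = 1e-9)
  # step at t = 5
  step <- ifelse(t < 5, 0, 1)
  expect_equal(latency20(step, t), 5, tolerance = 1e-9)
  # noiseless double Gaussian: root-find the closed form
  p <- hrf_params(a1 = 1, mu1 = 2, sigma1 = 2, a2 = -0.3, mu2 = 9, sigma2 = 3)
  curve <- hrf_curve(p, t)
  lat <- latency20(curve, t)
  f <- function(tt) hrf_curve(p, tt) - 0.2 * max(curve)
  root <- uniroot(f, c(-7, 2))$root
  expect_lt(abs(lat - root), 0.01 + 1e-9)
})

test_that("latency is invariant to affine rescaling of the signal", {
  t <- seq(-10, 20, by = 0.05)
  p <- hrf_params(a1 = 1, mu1 = 1, sigma1 = 2)
  curve <- hrf_curve(p, t)
  l0 <- latency20(curve, t)
  expect_equal(latency20(3.7 * curve + 11, t), l0)
  expect_equal(latency20(-2 * curve + 5, t), l0)  # absolute polarity
})

test_that("positive polarity tracks the positive extremum", {
  t <- seq(-10, 20, by = 0.05)
  # big deactivation, small activation
  curve <- 0.4 * exp(-(t - 0)^2 / 4) - exp(-(t - 8)^2 / 8)
  l_abs <- latency20(curve, t)
  l_pos <- latency20(curve, t, polarity = "positive")
  expect_lt(l_pos, l_abs)  # positive peak earlier than the deactivation
  pure_neg <- ifelse(t > 0, -exp(-(t - 5)^2 / 4), 0)
  expect_error(latency20(pure_neg, t, polarity = "positive"),
               "no positive deviation")
})

test_that("latency bootstrap is deterministic with degenerate-width CIs for
           identical rows", {
  t <- seq(-10, 20, by = 0.25)
  row <- hrf_curve(hrf_params(a1 = 1, mu1 = 3, sigma1 = 2), t)
  ens <- structure(list(mat = rbind(row, row, row), rel_time = t, dt = 0.25),
                   class = "locked_ensemble")
  b1 <- bootstrap_latency(ens, n = 50, seed = 11)
  expect_equal(b1$ci_lo, b1$ci_hi)
  expect_equal(b1$ci_lo, b1$latency)
  set.seed(6)
  ens$mat <- ens$mat + matrix(rnorm(3 * length(t), sd = 0.1), 3)
  b2 <- bootstrap_latency(ens, n = 100, seed = 7)
  b3 <- bootstrap_latency(ens, n = 100, seed = 7)
  expect_identical(b2, b3)
  expect_lte(b2$ci_lo, b2$ci_hi)
})

test_that("binned t-tests flag real offsets and respect pairing", {
  dt <- 0.25
  t <- seq(-10, 20, by = dt)
  set.seed(8)
  mk <- function(mat) structure(list(mat = mat, rel_time = t, dt = dt),
                                class = "locked_ensemble")
  noise <- mk(matrix(rnorm(20 * length(t), sd = 0.5), 20))
  shifted <- noise
  sel <- t >= 5 & t < 6
  shifted$mat[, sel] <- shifted$mat[, sel] + 10
  res <- binned_test(shifted)
  expect_true(res$significant[res$bin_start == 5])
  expect_false(any(res$significant[res$bin_start != 5]))
  # paired mode with identical ensembles: nothing significant
  paired <- binned_test(noise, ens2 = noise, mode = "paired")
  expect_false(any(paired$significant))
  expect_equal(unique(paired$p), 1)
  expect_error(binned_test(noise, ens2 = mk(noise$mat[1:5, ]),
                           mode = "paired"), "equal event counts")
})

test_that("SVD activity modes recover orthogonal generating modes", {
  t <- seq(-10, 20, by = 0.25)
  m1 <- sin(2 * pi * t / 15)
  m2 <- cos(2 * pi * t / 15)
  mat <- rbind(2 * m1, -1 * m1, 3 * m2)  # two orthogonal temporal modes
  modes <- pca_modes(mat)
  expect_equal(sum(modes$var_explained[1:2]), 1, tolerance = 1e-12)
  expect_equal(sum(modes$var_explained), 1, tolerance = 1e-12)
  # duplicated single profile -> one nonzero singular value
  dup <- pca_modes(rbind(m1, m1))
  expect_equal(dup$var_explained[1], 1, tolerance = 1e-12)
  # random matrix: fractions match the eigen-decomposition of the
  # uncentered cross-product
  set.seed(9)
  M <- matrix(rnorm(6 * 40), 6)
  ev <- eigen(M %*% t(M), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca_modes(M)$var_explained, ev / sum(ev), tolerance = 1e-10)
  # components orthogonal
  modes <- pca_modes(M)
  G <- modes$timecourses %*% t(modes$timecourses)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(pca_modes(matrix(0, 3, 10)), "rank-0|degenerate")
})
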