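# Arousal-locked ensembles: upsampling, window extraction, baseline
# centering, mean/SEM, 20%-latency with bootstrap CIs, time-binned t-tests,
# and PCA activity modes.

#' Linearly upsample a uniformly sampled series
#'
#' Linear interpolation to `factor` times the original sampling rate;
#' original samples are preserved exactly. Used to align BOLD data more
#' precisely with event times (e.g. TR 247 ms upsampled 4x to 61.75 ms).
#'
#' @param values numeric vector.
#' @param dt sampling interval (s).
#' @param factor integer >= 1, default 4.
#' @param t0 time of the first sample (s), default 0.
#' @return list with `values`, `dt` (= dt/factor), `t0`.
#' @export
upsample_series <- function(values, dt, factor = 4, t0 = 0) {
  if (factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  n <- length(values)
  if (factor == 1L) return(list(values = as.numeric(values), dt = dt, t0 = t0))
  t_in <- t0 + (seq_len(n) - 1L) * dt
  t_out <- t0 + (seq_len((n - 1L) * factor + 1L) - 1L) * (dt / factor)
  out <- approx(t_in, values, xout = t_out, method = "linear")$y
  # exact preservation on the original grid (approx is exact there up to fp)
  out[seq(1L, length(out), by = factor)] <- values
  list(values = out, dt = dt / factor, t0 = t0)
}

#' Extract event-locked windows into an ensemble matrix
#'
#' Each retained event contributes one row, aligned at the sample nearest
#' the event time, spanning `pre` seconds before to `post` seconds after.
#' Events flagged `excluded` and events whose window crosses the run
#' boundary are dropped (the latter with a message).
#'
#' @param values numeric vector (typically upsampled BOLD).
#' @param dt sampling interval (s).
#' @param event_times numeric vector of event times (s).
#' @param pre,post window extent before/after the event (s), defaults 10/20.
#' @param t0 time of the first sample (s), default 0.
#' @param excluded optional logical vector parallel to `event_times`.
#' @param subject optional per-event subject ids.
#' @return an object of class `locked_ensemble`: list with `mat`
#'   (events x timepoints), `rel_time` (s relative to the event; includes 0),
#'   `dt`, `event_times`, `subject`, `centered` flag.
#' @export
extract_windows <- function(values, dt, event_times, pre = 10, post = 20,
                            t0 = 0, excluded = NULL, subject = NULL) {
  n <- length(values)
  if (!is.null(excluded)) {
    keep0 <- !excluded
    event_times <- event_times[keep0]
    if (!is.null(subject)) subject <- subject[keep0]
  }
  n_pre <- round(pre / dt)
  n_post <- round(post / dt)
  rel_time <- (-n_pre:n_post) * dt
  idx0 <- round((event_times - t0) / dt) + 1L  # nearest sample to the event
  ok <- idx0 - n_pre >= 1L & idx0 + n_post <= n
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: window crosses run boundary")
  idx0 <- idx0[ok]
  if (!length(idx0)) stop("no valid events: empty ensemble", call. = FALSE)
  if (!is.null(subject)) subject <- subject[ok]
  mat <- t(vapply(idx0, function(i) values[(i - n_pre):(i + n_post)],
                  numeric(n_pre + n_post + 1L)))
  structure(list(mat = mat, rel_time = rel_time, dt = dt,
                 event_times = event_times[ok],
                 subject = subject, centered = FALSE),
            class = "locked_ensemble")
}

#' Center each ensemble row at its pre-event baseline
#'
#' Subtracts from each row its mean over the baseline window (default the
#' first 3 s of the window, -10 to -7 s relative to the event).
#'
#' @param ens a `locked_ensemble`.
#' @param window numeric pair (s relative to event), default `c(-10, -7)`.
#' @return the centered ensemble (idempotent).
#' @export
baseline_center <- function(ens, window = c(-10, -7)) {
  sel <- ens$rel_time >= window[1L] & ens$rel_time <= window[2L]
  if (!any(sel)) stop("baseline window outside ensemble time axis", call. = FALSE)
  ens$mat <- ens$mat - rowMeans(ens$mat[, sel, drop = FALSE])
  ens$centered <- TRUE
  ens$baseline_window <- window
  ens
}

#' Pointwise mean and standard error of an ensemble
#'
#' @param ens a `locked_ensemble`.
#' @return list with `mean`, `sem` (sample sd / sqrt(n events)), `rel_time`,
#'   `n`.
#' @export
ensemble_mean_sem <- function(ens) {
  n <- nrow(ens$mat)
  m <- colMeans(ens$mat)
  s <- if (n > 1L) apply(ens$mat, 2L, sd) / sqrt(n) else rep(0, ncol(ens$mat))
  list(mean = m, sem = s, rel_time = ens$rel_time, n = n)
}

#' Latency at 20% of the maximum (absolute or positive) deviation
#'
#' The baseline is the mean over `baseline_window`; the extremum is the
#' maximum absolute deviation from baseline over the whole window (or the
#' maximum positive deviation when `polarity = "positive"`). The latency is
#' the earliest time after the baseline window at which the deviation, on
#' the side of the extremum, reaches `threshold` times its magnitude.
#'
#' @param values mean event-locked series.
#' @param rel_time time axis (s relative to the event).
#' @param polarity `"absolute"` (default) or `"positive"`.
#' @param baseline_window numeric pair (s), default `c(-10, -7)`.
#' @param threshold fraction of the extremum, default 0.2.
#' @return latency (s relative to the event).
#' @export
latency20 <- function(values, rel_time, polarity = c("absolute", "positive"),
                      baseline_window = c(-10, -7), threshold = 0.2) {
  polarity <- match.arg(polarity)
  bsel <- rel_time >= baseline_window[1L] & rel_time <= baseline_window[2L]
  if (!any(bsel)) stop("baseline window outside time axis", call. = FALSE)
  dev <- values - mean(values[bsel])
  search <- rel_time > baseline_window[2L]
  if (polarity == "positive") {
    ext <- max(dev[search])
    if (ext <= 0) stop("degenerate signal: no positive deviation", call. = FALSE)
    signed <- dev
  } else {
    i_ext <- which.max(abs(dev[search]))
    ext_val <- dev[search][i_ext]
    if (ext_val == 0) stop("degenerate signal: zero extremum", call. = FALSE)
    ext <- abs(ext_val)
    signed <- dev * sign(ext_val)  # fold onto the side of the extremum
  }
  hit <- which(search & signed >= threshold * ext)
  if (!length(hit)) stop("threshold never reached", call. = FALSE)
  rel_time[hit[1L]]
}

#' Bootstrap confidence interval for the 20% latency
#'
#' Resamples ensemble rows (arousals) with replacement `n` times,
#' recomputes the mean series and its latency each time, and reports the
#' 2.5 and 97.5 percentiles. The point estimate comes from the full
#' ensemble. Deterministic for a fixed seed.
#'
#' @param ens a `locked_ensemble` (baseline-centered or not; centering is
#'   re-derived from the mean inside [latency20()]).
#' @param polarity,baseline_window,threshold passed to [latency20()].
#' @param n number of bootstrap resamples, default 1000.
#' @param seed RNG seed (required for reproducibility).
#' @return list with `latency`, `ci_lo`, `ci_hi`, `polarity`, `threshold`,
#'   `n_boot`, `n_failed` (resamples where the latency was undefined).
#' @export
bootstrap_latency <- function(ens, polarity = "absolute",
                              baseline_window = c(-10, -7), threshold = 0.2,
                              n = 1000, seed) {
  if (nrow(ens$mat) < 2L) stop("need >= 2 events to bootstrap", call. = FALSE)
  point <- latency20(colMeans(ens$mat), ens$rel_time, polarity,
                     baseline_window, threshold)
  lat <- with_seed(seed, {
    vapply(seq_len(n), function(b) {
      rows <- sample.int(nrow(ens$mat), replace = TRUE)
      m <- colMeans(ens$mat[rows, , drop = FALSE])
      tryCatch(latency20(m, ens$rel_time, polarity, baseline_window, threshold),
               error = function(e) NA_real_)
    }, numeric(1L))
  })
  n_failed <- sum(is.na(lat))
  if (n_failed == n) stop("all bootstrap resamples degenerate", call. = FALSE)
  ci <- pct_ci(lat)
  list(latency = point, ci_lo = ci$lo, ci_hi = ci$hi, polarity = polarity,
       threshold = threshold, n_boot = n, n_failed = n_failed)
}

#' Time-binned t-tests across an event-locked window
#'
#' Averages each event's signal within consecutive time bins (default 1 s)
#' and tests each bin with a two-sided t-test: one-sample against zero, or
#' paired against a second ensemble with the same events. P-values are
#' Bonferroni-corrected for the number of bins times the number of regions
#' in the testing family.
#'
#' @param ens a `locked_ensemble` (baseline-centered).
#' @param ens2 optional second ensemble for `mode = "paired"`.
#' @param bin bin width (s), default 1.
#' @param mode `"one-sample"` or `"paired"`.
#' @param n_rois number of regions in the correction family, default 1.
#' @param alpha family-wise significance level, default 0.05.
#' @return data.frame with `bin_start`, `bin_end`, `t`, `p`, `p_adj`,
#'   `significant`.
#' @export
binned_test <- function(ens, ens2 = NULL, bin = 1,
                        mode = c("one-sample", "paired"),
                        n_rois = 1, alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(ens2)) stop("paired mode needs `ens2`", call. = FALSE)
    if (nrow(ens2$mat) != nrow(ens$mat))
      stop("paired mode needs equal event counts", call. = FALSE)
  }
  t0 <- min(ens$rel_time)
  t1 <- max(ens$rel_time)
  n_bins <- round((t1 - t0) / bin)
  if (n_bins < 1L || abs((t1 - t0) - n_bins * bin) > ens$dt + 1e-9)
    stop("bins must tile the window exactly (within one sample)", call. = FALSE)
  edges <- seq(t0, by = bin, length.out = n_bins + 1L)
  fam <- n_bins * n_rois
  res <- lapply(seq_len(n_bins), function(k) {
    sel <- ens$rel_time >= edges[k] & ens$rel_time < edges[k + 1L]
    if (k == n_bins) sel <- sel | ens$rel_time == edges[k + 1L]
    x <- rowMeans(ens$mat[, sel, drop = FALSE])
    d <- if (mode == "paired") x - rowMeans(ens2$mat[, sel, drop = FALSE]) else x
    tt <- t_onesample(d)
    data.frame(bin_start = edges[k], bin_end = edges[k + 1L],
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(out$p * fam, 1)
  out$significant <- out$p_adj < alpha
  out
}

#' Principal activity modes across regions by singular value decomposition
#'
#' Takes the matrix of baseline-centered event-locked mean timeseries
#' (regions x timepoints) and decomposes it by SVD. Variance-explained
#' fractions are the squared singular values normalized to sum to one.
#'
#' @param mean_mat numeric matrix, regions x timepoints, of centered means.
#' @param roi_names optional rownames.
#' @return list with `timecourses` (components x timepoints), `loadings`
#'   (regions x components), `var_explained` (fractions summing to 1),
#'   `d` (singular values).
#' @export
pca_modes <- function(mean_mat, roi_names = rownames(mean_mat)) {
  mean_mat <- as.matrix(mean_mat)
  if (nrow(mean_mat) < 2L) stop("need >= 2 regions", call. = FALSE)
  s <- svd(mean_mat)
  tot <- sum(s$d^2)
  if (tot == 0) stop("degenerate (rank-0) input matrix", call. = FALSE)
  loadings <- s$u
  rownames(loadings) <- roi_names
  list(timecourses = t(s$v) * s$d,  # component k scaled by its singular value
       loadings = loadings,
       var_explained = s$d^2 / tot,
       d = s$d)
}
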