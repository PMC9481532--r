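# Cross-ROI temporal sequencing: cross-correlation lags against a global
# reference, flat and hierarchical bootstrap confidence intervals, sequence
# summaries, and breathhold-based hemodynamic lag correction.

#' Cross-correlation lag between a region and a reference
#'
#' Computes the Pearson correlation over overlapping samples at every
#' integer-step shift within `max_lag` and returns the shift maximizing the
#' correlation. Positive lag means the region lags (follows) the reference;
#' negative means it leads. Ties are broken toward the smallest absolute
#' lag, then negative before positive. With `positive_only = TRUE` the
#' search is restricted to shifts with positive correlation (used for
#' within-class sequences where positive coupling is established).
#'
#' @param x region mean series.
#' @param y reference mean series (same time axis and length).
#' @param dt sampling interval (s).
#' @param max_lag maximum absolute lag searched (s), default 10.
#' @param positive_only restrict to positive correlations, default FALSE.
#' @return list with `lag` (s), `r` (peak correlation), `shifts` and
#'   `r_all` (the full correlation-by-shift profile).
#' @export
xcorr_lag <- function(x, y, dt, max_lag = 10, positive_only = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  K <- round(max_lag / dt)
  r <- .xcorr_shifts(x, y, as.integer(K))
  K <- (length(r) - 1L) %/% 2L
  shifts <- (-K:K) * dt
  cand <- which(is.finite(r))
  if (!length(cand)) stop("degenerate correlation: zero variance at all shifts",
                          call. = FALSE)
  if (positive_only) {
    cand <- cand[r[cand] > 0]
    if (!length(cand)) stop("no positive correlation at any shift", call. = FALSE)
  }
  rmax <- max(r[cand])
  best <- cand[r[cand] >= rmax - 1e-12]
  # tie-break: smallest |lag|, then negative before positive
  best <- best[order(abs(shifts[best]), shifts[best])]
  i <- best[1L]
  list(lag = shifts[i], r = r[i], shifts = shifts, r_all = r)
}

# Build per-ROI and reference means from a list of ensembles (one
# `locked_ensemble` per ROI, sharing the event set), optionally restricted
# to a row resample. The reference is the average of the ROI means
# (equal-weight "whole structure" signal), rebuilt from the same rows so
# its dependence on the resample is preserved.
.roi_and_ref_means <- function(ens_list, rows = NULL) {
  means <- lapply(ens_list, function(e) {
    m <- if (is.null(rows)) e$mat else e$mat[rows, , drop = FALSE]
    colMeans(m)
  })
  ref <- Reduce(`+`, means) / length(means)
  list(means = means, ref = ref)
}

#' Cross-correlation lags for a set of regions with bootstrap CIs
#'
#' Point estimates use the full ensembles; confidence intervals come from
#' resampling events with replacement (the same resample indices applied to
#' every region, so the reference — the average of the region means — stays
#' internally consistent), recomputing all lags each time, and taking the
#' 2.5/97.5 percentiles over `n` resamples.
#'
#' @param ens_list named list of `locked_ensemble`s, one per region, all
#'   sharing the same event rows.
#' @param dt sampling interval (s); defaults to the ensembles' step.
#' @param max_lag,positive_only passed to [xcorr_lag()].
#' @param n bootstrap resamples, default 1000.
#' @param seed RNG seed.
#' @param reference optional fixed reference series; by default the
#'   equal-weight average of region means, rebuilt per resample.
#' @return data.frame with `roi`, `lag`, `r`, `ci_lo`, `ci_hi`, `n_boot`.
#' @export
bootstrap_lags <- function(ens_list, dt = NULL, max_lag = 10,
                           positive_only = FALSE, n = 1000, seed,
                           reference = NULL) {
  if (is.null(names(ens_list)))
    names(ens_list) <- paste0("roi", seq_along(ens_list))
  if (is.null(dt)) dt <- ens_list[[1L]]$dt
  n_ev <- nrow(ens_list[[1L]]$mat)
  stopifnot(all(vapply(ens_list, function(e) nrow(e$mat), 0L) == n_ev))
  full <- .roi_and_ref_means(ens_list)
  ref_full <- if (is.null(reference)) full$ref else reference
  point <- lapply(full$means, function(m)
    xcorr_lag(m, ref_full, dt, max_lag, positive_only))
  boot <- with_seed(seed, {
    vapply(seq_len(n), function(b) {
      rows <- sample.int(n_ev, replace = TRUE)
      rs <- .roi_and_ref_means(ens_list, rows)
      ref <- if (is.null(reference)) rs$ref else reference
      vapply(rs$means, function(m) {
        tryCatch(xcorr_lag(m, ref, dt, max_lag, positive_only)$lag,
                 error = function(e) NA_real_)
      }, numeric(1L))
    }, numeric(length(ens_list)))
  })
  boot <- matrix(boot, nrow = length(ens_list))
  bad <- rowMeans(is.na(boot))
  if (any(bad > 0.5))
    stop("unstable estimate: degenerate correlation in > 50% of resamples for ",
         paste(names(ens_list)[bad > 0.5], collapse = ", "), call. = FALSE)
  ci <- apply(boot, 1L, pct_ci)
  data.frame(roi = names(ens_list),
             lag = vapply(point, `[[`, 0, "lag"),
             r = vapply(point, `[[`, 0, "r"),
             ci_lo = vapply(ci, `[[`, 0, "lo"),
             ci_hi = vapply(ci, `[[`, 0, "hi"),
             n_boot = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical (subject-level) bootstrap of cross-correlation lags
#'
#' Resamples subjects with replacement, then arousals with replacement
#' within each drawn subject, accumulating until the total number of
#' resampled arousals reaches `target_total` (by default the observed
#' total). Lags against the rebuilt reference are recomputed per resample;
#' CIs are the 2.5/97.5 percentiles. With a single subject this falls back
#' to the flat bootstrap with a warning.
#'
#' @param subj_ens list over subjects; each element a named list of
#'   `locked_ensemble`s (one per region, same region names across subjects).
#' @param dt sampling interval (s); defaults to the first ensemble's step.
#' @param target_total minimum total arousals per resample; default the
#'   observed total.
#' @param max_lag,positive_only passed to [xcorr_lag()].
#' @param n bootstrap resamples, default 1000.
#' @param seed RNG seed.
#' @return data.frame as in [bootstrap_lags()].
#' @export
hierarchical_bootstrap_lags <- function(subj_ens, dt = NULL,
                                        target_total = NULL, max_lag = 10,
                                        positive_only = FALSE, n = 1000,
                                        seed) {
  n_subj <- length(subj_ens)
  rois <- names(subj_ens[[1L]])
  if (is.null(dt)) dt <- subj_ens[[1L]][[1L]]$dt
  n_ev <- vapply(subj_ens, function(s) nrow(s[[1L]]$mat), 0L)
  if (is.null(target_total)) target_total <- sum(n_ev)
  if (n_subj < 2L) {
    warning("single subject: falling back to flat bootstrap", call. = FALSE)
    return(bootstrap_lags(subj_ens[[1L]], dt, max_lag, positive_only, n, seed))
  }
  # point estimate: pool all subjects' events
  pooled <- lapply(rois, function(r) {
    mat <- do.call(rbind, lapply(subj_ens, function(s) s[[r]]$mat))
    list(mat = mat)
  })
  names(pooled) <- rois
  full <- .roi_and_ref_means(pooled)
  point <- lapply(full$means, function(m)
    xcorr_lag(m, full$ref, dt, max_lag, positive_only))
  boot <- with_seed(seed, {
    vapply(seq_len(n), function(b) {
      rows_by_roi <- lapply(rois, function(r) NULL)
      names(rows_by_roi) <- rois
      total <- 0L
      acc <- lapply(rois, function(r) list())
      names(acc) <- rois
      while (total < target_total) {
        s <- sample.int(n_subj, 1L)
        take <- sample.int(n_ev[s], replace = TRUE)
        for (r in rois)
          acc[[r]][[length(acc[[r]]) + 1L]] <-
            subj_ens[[s]][[r]]$mat[take, , drop = FALSE]
        total <- total + n_ev[s]
      }
      means <- lapply(acc, function(blocks) colMeans(do.call(rbind, blocks)))
      ref <- Reduce(`+`, means) / length(means)
      vapply(means, function(m) {
        tryCatch(xcorr_lag(m, ref, dt, max_lag, positive_only)$lag,
                 error = function(e) NA_real_)
      }, numeric(1L))
    }, numeric(length(rois)))
  })
  boot <- matrix(boot, nrow = length(rois))
  ci <- apply(boot, 1L, pct_ci)
  data.frame(roi = rois,
             lag = vapply(point, `[[`, 0, "lag"),
             r = vapply(point, `[[`, 0, "r"),
             ci_lo = vapply(ci, `[[`, 0, "lo"),
             ci_hi = vapply(ci, `[[`, 0, "hi"),
             n_boot = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Order regions by lag and summarize the sequence range
#'
#' @param lag_table data.frame with `roi` and `lag` columns (e.g. from
#'   [bootstrap_lags()]).
#' @return list with `order` (ROI names sorted by ascending lag, i.e.
#'   leaders first), `range` (max lag - min lag, s), and the sorted table.
#' @export
lag_sequence <- function(lag_table) {
  if (nrow(lag_table) < 2L) stop("need >= 2 regions", call. = FALSE)
  o <- order(lag_table$lag)
  sorted <- lag_table[o, , drop = FALSE]
  list(order = sorted$roi, range = max(lag_table$lag) - min(lag_table$lag),
       table = sorted)
}

#' Breathhold-release-locked lags (vascular latency control)
#'
#' Extracts windows around breathhold-release events (default 20 s before
#' to 20 s after release), averages per region, and applies the same
#' cross-correlation machinery against the average reference. Motion
#' exclusion is applied identically to arousals when a motion trace is
#' given.
#'
#' @param roi_values named list of numeric vectors (one per region, shared
#'   grid) — typically upsampled breathhold-run BOLD.
#' @param dt sampling interval (s).
#' @param release_times breathhold release event times (s).
#' @param pre,post window extent (s), defaults 20/20.
#' @param t0 time of the first sample, default 0.
#' @param motion optional `motion_trace` for exclusion (threshold 0.3 mm).
#' @param max_lag maximum lag searched (s), default 10.
#' @param n,seed bootstrap settings; `n = 0` skips CIs.
#' @return data.frame as in [bootstrap_lags()] (with NA CIs when `n = 0`).
#' @export
breathhold_lags <- function(roi_values, dt, release_times, pre = 20,
                            post = 20, t0 = 0, motion = NULL, max_lag = 10,
                            n = 1000, seed = 1) {
  excluded <- NULL
  if (!is.null(motion)) {
    ev <- data.frame(time = release_times, excluded = FALSE)
    ev <- apply_motion_exclusion(ev, motion, window = c(-pre, post))
    excluded <- ev$excluded
  }
  ens <- lapply(roi_values, function(v)
    extract_windows(v, dt, release_times, pre = pre, post = post, t0 = t0,
                    excluded = excluded))
  ens <- lapply(ens, baseline_center, window = c(-pre, -pre + 3))
  if (n > 0) return(bootstrap_lags(ens, dt, max_lag, n = n, seed = seed))
  full <- .roi_and_ref_means(ens)
  point <- lapply(full$means, function(m) xcorr_lag(m, full$ref, dt, max_lag))
  data.frame(roi = names(ens),
             lag = vapply(point, `[[`, 0, "lag"),
             r = vapply(point, `[[`, 0, "r"),
             ci_lo = NA_real_, ci_hi = NA_real_, n_boot = 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correct arousal lags for regional vascular (breathhold) delay
#'
#' Subtracts each region's average breathhold lag from its behavioral
#' arousal lag, removing the purely hemodynamic component of the sequence.
#'
#' @param arousal_lags,breathhold_lags data.frames with `roi` and `lag`
#'   columns covering the same region set.
#' @return data.frame with `roi`, `lag` (corrected), `arousal_lag`,
#'   `breathhold_lag`.
#' @export
hemodynamic_correct <- function(arousal_lags, breathhold_lags) {
  if (!setequal(arousal_lags$roi, breathhold_lags$roi))
    stop("region sets differ between arousal and breathhold lags",
         call. = FALSE)
  bh <- breathhold_lags$lag[match(arousal_lags$roi, breathhold_lags$roi)]
  data.frame(roi = arousal_lags$roi,
             lag = arousal_lags$lag - bh,
             arousal_lag = arousal_lags$lag,
             breathhold_lag = bh,
             stringsAsFactors = FALSE)
}
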