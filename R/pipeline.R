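# End-to-end orchestration: behavior -> physio -> locked -> lags -> hrffit
# (-> spectral when EEG is present), with one parameter set and a
# provenance block on every output.

#' Default pipeline parameters
#'
#' Every stage threshold with its standard value: arousal gap 20 s, motion
#' 0.3 mm, window -10/+20 s, baseline -10/-7 s, 4x upsampling, 1000
#' bootstrap resamples, sliding GLM 1000/400 s with harmonics 1-2, max lag
#' 10 s, alpha band 8-13 Hz, HRF onset fraction 0.1.
#'
#' @param ... overrides for any element.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(min_gap = 20, fd_threshold = 0.3, window = c(-10, 20),
            baseline = c(-10, -7), upsample = 4, n_boot = 1000,
            boot_seed = 1, max_lag = 10, clean_physio = TRUE,
            glm_window = 1000, glm_step = 400, harmonics = 1:2,
            alpha_band = c(8, 13), eeg_window = 2, eeg_step = 1,
            eeg_tapers = 3, onset_fraction = 0.1, hrf_restarts = 8,
            bin = 1, target_total = NULL)
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

# Identify thalamic vs cortical columns of a ROI table.
.roi_groups <- function(roi_names, params) {
  thal <- params$thalamic_rois
  if (is.null(thal))
    thal <- roi_names[roi_names %in% THALAMIC_NUCLEI |
                        startsWith(roi_names, "thal")]
  cort <- params$cortical_rois
  if (is.null(cort)) cort <- setdiff(roi_names, thal)
  list(thalamic = thal, cortical = cort)
}

# Build baseline-centered locked ensembles for every ROI.
.build_ensembles <- function(roi, tr, events, params, subject = NULL) {
  roi_names <- setdiff(names(roi), "time")
  t0 <- roi$time[1L]
  lapply(stats::setNames(roi_names, roi_names), function(nm) {
    up <- upsample_series(roi[[nm]], tr, params$upsample, t0 = t0)
    ens <- extract_windows(up$values, up$dt, events$time,
                           pre = -params$window[1L], post = params$window[2L],
                           t0 = up$t0, excluded = events$excluded,
                           subject = subject)
    baseline_center(ens, params$baseline)
  })
}

# Average several ROI ensembles into one aggregate-region ensemble.
.aggregate_ensemble <- function(ens_list) {
  agg <- ens_list[[1L]]
  agg$mat <- Reduce(`+`, lapply(ens_list, `[[`, "mat")) / length(ens_list)
  agg
}

#' Run the full arousal analysis pipeline on a session
#'
#' Stages: arousal detection from the button-press log; motion exclusion;
#' optional sliding-window physiological regression; arousal-locked
#' ensembles per ROI; whole-thalamus and whole-cortex latencies with
#' bootstrap CIs; PCA activity modes; thalamic cross-correlation lag
#' sequence with bootstrap CIs (all arousals, and sustained/transient
#' subsets with the positive-correlation restriction); per-nucleus HRF fits
#' and onset times; time-binned cortical t-tests; and, when an EEG channel
#' is present, the alpha-power pre/post test. When `out_dir` is given,
#' every table is written as TSV alongside a JSON provenance block carrying
#' the full config, its hash, and the seed.
#'
#' @param session an `arousal_session` (from [make_session()] or assembled
#'   from files), with `roi`, `tr`, `events`, `motion`, optionally
#'   `physio` and `eeg`.
#' @param params parameter list from [pipeline_params()].
#' @param out_dir optional output directory.
#' @return list with `arousals`, `ensembles`, `latency` (whole thalamus and
#'   cortex), `pca`, `lags` (all/sustained/transient), `sequence`, `hrf`
#'   (per-nucleus fits and onset table), `binned`, `alpha` (or NULL),
#'   `provenance`.
#' @export
run_pipeline <- function(session, params = pipeline_params(),
                         out_dir = NULL) {
  roi <- session$roi
  tr <- session$tr
  t0 <- roi$time[1L]
  run_end <- max(roi$time)

  # -- behavior -------------------------------------------------------------
  presses <- session$events$onset[session$events$trial_type == "press"]
  arousals <- detect_arousals(presses, run_start = t0, run_end = run_end,
                              min_gap = params$min_gap)
  if (!nrow(arousals)) stop("no behavioral arousals detected", call. = FALSE)
  if (!is.null(session$motion)) {
    motion <- framewise_displacement(session$motion, tr)
    arousals <- apply_motion_exclusion(arousals, motion,
                                       threshold = params$fd_threshold,
                                       window = params$window,
                                       run_start = t0)
  }

  # -- physio cleaning ------------------------------------------------------
  if (isTRUE(params$clean_physio) && !is.null(session$physio)) {
    ph_c <- cardiac_phase(session$physio$cardiac, session$physio$fs,
                          bold_time = roi$time, t0 = session$physio$t0)
    ph_r <- respiratory_phase(session$physio$resp, session$physio$fs,
                              bold_time = roi$time, t0 = session$physio$t0)
    for (nm in setdiff(names(roi), "time"))
      roi[[nm]] <- suppressMessages(
        dynamic_retroicor(roi[[nm]], tr, ph_c$phase, ph_r$phase,
                          window = params$glm_window, step = params$glm_step,
                          harmonics = params$harmonics))$values
  }

  # -- locked ensembles -----------------------------------------------------
  ens <- .build_ensembles(roi, tr, arousals, params)
  groups <- .roi_groups(names(ens), params)
  thal_ens <- ens[groups$thalamic]
  cort_ens <- ens[groups$cortical]

  latency <- list()
  if (length(thal_ens)) {
    agg <- .aggregate_ensemble(thal_ens)
    latency$thalamus <- bootstrap_latency(agg, "absolute", params$baseline,
                                          n = params$n_boot,
                                          seed = params$boot_seed)
  }
  if (length(cort_ens)) {
    agg <- .aggregate_ensemble(cort_ens)
    latency$cortex <- bootstrap_latency(agg, "absolute", params$baseline,
                                        n = params$n_boot,
                                        seed = params$boot_seed)
  }

  # -- PCA modes ------------------------------------------------------------
  mean_mat <- t(vapply(ens, function(e) colMeans(e$mat),
                       numeric(ncol(ens[[1L]]$mat))))
  pca <- pca_modes(mean_mat)

  # -- lag sequence ---------------------------------------------------------
  lags <- list()
  sequence <- NULL
  if (length(thal_ens) >= 2L) {
    lags$all <- bootstrap_lags(thal_ens, max_lag = params$max_lag,
                               n = params$n_boot, seed = params$boot_seed)
    sequence <- lag_sequence(lags$all)
    kept <- arousals[!arousals$excluded, , drop = FALSE]
    for (cls in c("sustained", "transient")) {
      rows <- which(kept$class == cls)
      if (length(rows) >= 2L) {
        sub <- lapply(thal_ens, function(e) {
          e$mat <- e$mat[rows, , drop = FALSE]; e
        })
        lags[[cls]] <- tryCatch(
          bootstrap_lags(sub, max_lag = params$max_lag, positive_only = TRUE,
                         n = params$n_boot, seed = params$boot_seed),
          error = function(e) NULL)
      }
    }
  }

  # -- HRF fits -------------------------------------------------------------
  hrf <- NULL
  if (length(thal_ens)) {
    fits <- lapply(thal_ens, function(e)
      fit_hrf(colMeans(e$mat), e$rel_time, restarts = params$hrf_restarts,
              seed = params$boot_seed))
    hrf <- list(fits = fits,
                onsets = data.frame(
                  roi = names(fits),
                  onset = vapply(fits, `[[`, 0, "onset"),
                  rmse = vapply(fits, `[[`, 0, "rmse"),
                  stringsAsFactors = FALSE, row.names = NULL))
  }

  # -- binned cortical tests ------------------------------------------------
  binned <- NULL
  if (length(cort_ens)) {
    binned <- lapply(cort_ens, binned_test, bin = params$bin,
                     n_rois = length(cort_ens))
  }

  # -- spectral (EEG) -------------------------------------------------------
  alpha <- NULL
  if (!is.null(session$eeg)) {
    spec <- multitaper_spectrogram(session$eeg$values, session$eeg$fs,
                                   window = params$eeg_window,
                                   step = params$eeg_step,
                                   tapers = params$eeg_tapers,
                                   t0 = session$eeg$t0)
    bp <- band_power(spec, params$alpha_band)
    kept_t <- arousals$time[!arousals$excluded]
    alpha <- c(prepost_test(bp$values, bp$times, kept_t), list(power = bp))
  }

  prov <- .provenance(params, params$boot_seed)
  out <- list(arousals = arousals, ensembles = ens, latency = latency,
              pca = pca, lags = lags, sequence = sequence, hrf = hrf,
              binned = binned, alpha = alpha, provenance = prov)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

# Write the headline tables with a provenance block.
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ar <- res$arousals
  ar$trial_type <- paste0("arousal_", ar$class)
  write_events(data.frame(onset = ar$time, duration = 0,
                          trial_type = ar$trial_type,
                          excluded = ar$excluded),
               file.path(out_dir, "arousals_events.tsv"))
  if (!is.null(res$latency) && length(res$latency)) {
    lt <- do.call(rbind, lapply(names(res$latency), function(nm) {
      l <- res$latency[[nm]]
      data.frame(region = nm, latency_s = l$latency, ci_lo = l$ci_lo,
                 ci_hi = l$ci_hi)
    }))
    write.table(lt, file.path(out_dir, "latency.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  for (nm in names(res$lags))
    if (!is.null(res$lags[[nm]]))
      write.table(res$lags[[nm]],
                  file.path(out_dir, paste0("lags_", nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$sequence))
    jsonlite::write_json(list(order = res$sequence$order,
                              range_s = res$sequence$range,
                              provenance = res$provenance),
                         file.path(out_dir, "sequence.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$hrf))
    write.table(res$hrf$onsets, file.path(out_dir, "hrf_onsets.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$pca))
    write.table(data.frame(component = seq_along(res$pca$var_explained),
                           var_explained = res$pca$var_explained),
                file.path(out_dir, "pca_variance.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
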