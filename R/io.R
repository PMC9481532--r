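# Plain-text readers and writers: ROI tables and event logs as TSV
# (BIDS-style events), physio waveforms as TSV plus a JSON sidecar, ground
# truth and provenance as JSON.

#' Read / write a ROI timeseries table
#'
#' Tab-separated table whose first column is `time` (s, uniform) and whose
#' remaining columns are one ROI each.
#'
#' @param path file path.
#' @param roi data.frame to write (`time` first).
#' @return `read_roi_table`: the data.frame; the TR can be recovered as
#'   `diff(roi$time)[1]`.
#' @export
read_roi_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "time") stop("first column must be `time`", call. = FALSE)
  df
}

#' @rdname read_roi_table
#' @export
write_roi_table <- function(roi, path) {
  write.table(roi, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated with columns `onset` (s), `duration` (s), `trial_type`
#' (e.g. `press`, `breathhold_release`, `arousal_sustained`).
#'
#' @param path file path.
#' @param events data.frame to write.
#' @export
read_events <- function(path) {
  ev <- read.delim(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file must have onset/duration/trial_type columns",
         call. = FALSE)
  ev
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a physiological recording (waveform TSV + JSON sidecar)
#'
#' The waveform table has columns `cardiac` and `resp`; the sidecar
#' `<prefix>.json` holds `sampling_rate` (Hz) and `start_time` (s).
#'
#' @param prefix path prefix; writes/reads `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param physio list with `cardiac`, `resp`, `fs`, `t0`.
#' @export
write_physio <- function(physio, prefix) {
  write.table(data.frame(cardiac = physio$cardiac, resp = physio$resp),
              paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(sampling_rate = physio$fs,
                            start_time = physio$t0),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_physio
#' @export
read_physio <- function(prefix) {
  wf <- read.delim(paste0(prefix, ".tsv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  list(cardiac = wf$cardiac, resp = wf$resp,
       fs = meta$sampling_rate, t0 = meta$start_time)
}

#' Write a synthetic session to a directory
#'
#' Writes `roi.tsv`, `events.tsv`, `motion.tsv` (6 columns), the physio
#' pair `physio.tsv`/`physio.json`, and the ground truth as
#' `ground_truth.json` (component traces omitted).
#'
#' @param session an `arousal_session`.
#' @param dir output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roi_table(session$roi, file.path(dir, "roi.tsv"))
  write_events(session$events, file.path(dir, "events.tsv"))
  if (!is.null(session$motion)) {
    mp <- as.data.frame(session$motion)
    names(mp) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    write.table(mp, file.path(dir, "motion.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (!is.null(session$physio))
    write_physio(session$physio, file.path(dir, "physio"))
  gt <- session$truth
  if (!is.null(gt$hrf)) gt$hrf <- lapply(gt$hrf, unclass)
  for (f in c("lags", "amplitudes", "delays"))
    if (!is.null(gt[[f]])) gt[[f]] <- as.list(gt[[f]])
  gt$components <- NULL
  gt$clean <- NULL
  gt$cardiac_freq <- NULL
  gt$resp_freq <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Provenance block attached to every pipeline output file set.
.provenance <- function(params, seed) {
  cfg_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  list(config = params, config_hash = fnv1a_hex(as.character(cfg_json)),
       seed = seed, package_version = as.character(utils::packageVersion("arousalseq")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
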