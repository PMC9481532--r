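# Behavioral arousal detection from button-press logs, motion-based
# exclusion, and the sustained/transient classification.

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus 50 mm times the sum of
#' absolute differences of the three rotations (rad), i.e. rotations are
#' converted to arc length on a 50 mm sphere. The first volume has FD = 0.
#'
#' @param mp numeric matrix with 6 columns (3 translations in mm, then 3
#'   rotations in rad), one row per volume; or a precomputed FD vector.
#' @param tr repetition time (s).
#' @param radius rotation-to-displacement radius (mm), default 50.
#' @return an object of class `motion_trace`: list with `fd` (mm) and `tr`.
#' @export
framewise_displacement <- function(mp, tr, radius = 50) {
  if (is.null(dim(mp))) {
    fd <- as.numeric(mp)
    if (any(fd < 0)) stop("FD values must be non-negative", call. = FALSE)
  } else {
    mp <- as.matrix(mp)
    if (ncol(mp) != 6L)
      stop("motion parameters must have 6 columns (3 translations mm, ",
           "3 rotations rad)", call. = FALSE)
    if (nrow(mp) < 2L) stop("need at least 2 volumes", call. = FALSE)
    d <- abs(diff(mp))
    fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
              radius * rowSums(d[, 4:6, drop = FALSE]))
  }
  structure(list(fd = fd, tr = tr), class = "motion_trace")
}

#' Detect behavioral arousals in a button-press log
#'
#' A behavioral arousal is the first button-press after at least `min_gap`
#' seconds of unresponsiveness. Silence from the run start counts toward the
#' gap (unresponsiveness, not a prior press, is the defining condition). The
#' number of responses attributed to an arousal counts the triggering press
#' plus all presses before the next silence of `min_gap` or more, and the
#' class follows [classify_arousal()].
#'
#' @param presses numeric vector of press onset times (s), any order.
#' @param run_start,run_end run boundaries (s); presses must lie within.
#' @param min_gap minimum unresponsive duration defining an arousal (s),
#'   default 20.
#' @return data.frame with columns `time`, `gap` (preceding unresponsive
#'   duration, s), `n_responses`, `class`, `excluded` (logical, all FALSE
#'   until [apply_motion_exclusion()] is run).
#' @export
#' @examples
#' detect_arousals(c(5, 30, 31, 32), run_start = 0, run_end = 120)
detect_arousals <- function(presses, run_start = 0, run_end = NULL,
                            min_gap = 20) {
  presses <- sort(as.numeric(presses))
  if (is.null(run_end)) run_end <- if (length(presses)) max(presses) else run_start
  if (length(presses) && (min(presses) < run_start || max(presses) > run_end))
    stop("press times must lie within [run_start, run_end]", call. = FALSE)
  empty <- data.frame(time = numeric(0), gap = numeric(0),
                      n_responses = integer(0), class = character(0),
                      excluded = logical(0), stringsAsFactors = FALSE)
  if (!length(presses)) return(empty)
  prev <- c(run_start, head(presses, -1L))
  gap <- presses - prev
  is_arousal <- gap >= min_gap
  if (!any(is_arousal)) return(empty)
  idx <- which(is_arousal)
  # responses in [arousal, next >= min_gap silence): presses up to (but not
  # including) the next arousal-triggering press
  nxt <- c(idx[-1L], length(presses) + 1L)
  n_resp <- nxt - idx
  data.frame(time = presses[idx], gap = gap[idx],
             n_responses = as.integer(n_resp),
             class = classify_arousal(n_resp),
             excluded = FALSE, stringsAsFactors = FALSE)
}

#' Classify arousals by the number of subsequent responses
#'
#' Sustained arousals have five or more button-press responses (counting the
#' triggering press), transient arousals two or fewer; counts of 3 or 4 form
#' an intermediate band that is excluded from two-class comparisons.
#'
#' @param n_responses integer vector of response counts.
#' @return character vector in `c("sustained", "transient", "intermediate")`.
#' @export
classify_arousal <- function(n_responses) {
  out <- rep("intermediate", length(n_responses))
  out[n_responses >= 5] <- "sustained"
  out[n_responses <= 2] <- "transient"
  out
}

#' Flag arousals whose peri-event window contains high motion
#'
#' An arousal is excluded when framewise displacement exceeds `threshold`
#' (mm) at any volume within `window` (s, relative to the arousal). Windows
#' are clipped at the run edges; a window falling entirely outside the
#' motion trace is an error.
#'
#' @param events data.frame from [detect_arousals()].
#' @param motion a `motion_trace` from [framewise_displacement()].
#' @param threshold FD exclusion threshold (mm), default 0.3.
#' @param window numeric pair, window relative to arousal (s), default
#'   `c(-10, 20)`.
#' @param run_start time of the first motion sample (s), default 0.
#' @return `events` with the `excluded` column updated.
#' @export
apply_motion_exclusion <- function(events, motion, threshold = 0.3,
                                   window = c(-10, 20), run_start = 0) {
  stopifnot(inherits(motion, "motion_trace"))
  n <- length(motion$fd)
  t_motion <- run_start + (seq_len(n) - 1L) * motion$tr
  run_end <- t_motion[n]
  if (!nrow(events)) return(events)
  excl <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    lo <- events$time[i] + window[1L]
    hi <- events$time[i] + window[2L]
    sel <- t_motion >= lo & t_motion <= hi
    if (!any(sel))
      stop("arousal window [", lo, ", ", hi, "] s not covered by motion trace",
           call. = FALSE)
    excl[i] <- max(motion$fd[sel]) > threshold
  }
  events$excluded <- excl
  events
}

#' Split classified arousals into sustained and transient sets
#'
#' Intermediate arousals (3 or 4 responses) are excluded from both sets.
#' Empty classes are reported with a warning and returned empty.
#'
#' @param events data.frame with a `class` column ([detect_arousals()]).
#' @return list with elements `sustained` and `transient`, each a subset of
#'   `events`.
#' @export
split_by_class <- function(events) {
  out <- list(sustained = events[events$class == "sustained", , drop = FALSE],
              transient = events[events$class == "transient", , drop = FALSE])
  for (cls in names(out))
    if (!nrow(out[[cls]])) warning("no ", cls, " arousals", call. = FALSE)
  out
}
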