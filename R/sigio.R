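#' Continuous extracellular recording
#'
#' Container for a uniformly sampled voltage trace. All times are absolute
#' seconds from recording start; peri-stimulus quantities elsewhere in the
#' package are reported in milliseconds, converted centrally by [ms_to_s()].
#'
#' @param samples numeric vector of voltage samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param start_time recording start in seconds (default 0).
#' @param channel_id character channel label.
#' @param excluded_intervals two-column matrix (or NULL) of `[t0, t1)` blanked
#'   intervals in seconds, e.g. the amplifier grounding window around each
#'   stimulus. Must be sorted, non-overlapping and inside the record.
#'
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, fs, start_time = 0,
                                 channel_id = "ch1",
                                 excluded_intervals = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  samples <- as.numeric(samples)
  if (is.null(excluded_intervals)) {
    excluded_intervals <- matrix(numeric(0), ncol = 2L)
  } else {
    excluded_intervals <- matrix(as.numeric(excluded_intervals), ncol = 2L)
    if (nrow(excluded_intervals) > 0L) {
      o <- order(excluded_intervals[, 1L])
      excluded_intervals <- excluded_intervals[o, , drop = FALSE]
      if (any(excluded_intervals[, 2L] < excluded_intervals[, 1L]))
        stop("excluded intervals must have t1 >= t0")
      if (nrow(excluded_intervals) > 1L &&
          any(excluded_intervals[-1L, 1L] <
              excluded_intervals[-nrow(excluded_intervals), 2L]))
        stop("excluded intervals must be non-overlapping")
    }
  }
  structure(
    list(samples = samples, fs = fs, start_time = start_time,
         channel_id = channel_id, excluded_intervals = excluded_intervals),
    class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf(
    "<continuous_recording> channel %s: %d samples @ %g Hz (%.3f s), %d excluded interval(s)\n",
    x$channel_id, length(x$samples), x$fs, length(x$samples) / x$fs,
    nrow(x$excluded_intervals)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [continuous_recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$fs

#' Time axis of a recording
#' @param rec a [continuous_recording()].
#' @return numeric vector of sample times in seconds.
#' @export
rec_times <- function(rec)
  rec$start_time + (seq_along(rec$samples) - 1L) / rec$fs

#' Stimulus log
#'
#' One row per delivered TMS pulse. Consecutive onsets must be separated by at
#' least the trial window length so peri-stimulus windows never overlap.
#'
#' @param onsets stimulus onset times in seconds, strictly increasing.
#' @param intensity_pct_mt intensity as percent of motor threshold, recycled.
#' @param orientation induced-current orientation, `"ML"` or `"PA"`, recycled.
#' @param pulse_type `"monophasic"`, `"biphasic"` or `"burst"`, recycled.
#' @param animal_id animal identifier, recycled.
#' @param intensity_pct_mso optional intensity as percent maximum stimulator
#'   output.
#'
#' @return A `stimulus_log`, which is a data.frame with one row per stimulus.
#' @export
stimulus_log <- function(onsets, intensity_pct_mt, orientation = "ML",
                         pulse_type = "monophasic", animal_id = "a1",
                         intensity_pct_mso = NA_real_) {
  onsets <- as.numeric(onsets)
  if (length(onsets) > 1L && any(diff(onsets) <= 0))
    stop("stimulus onsets must be strictly increasing")
  if (!all(orientation %in% c("ML", "PA")))
    stop("orientation must be 'ML' or 'PA'")
  if (!all(pulse_type %in% c("monophasic", "biphasic", "burst")))
    stop("unknown pulse_type")
  out <- data.frame(
    onset = onsets,
    intensity_pct_mt = rep_len(as.numeric(intensity_pct_mt),
                               length(onsets)),
    intensity_pct_mso = rep_len(as.numeric(intensity_pct_mso),
                                length(onsets)),
    orientation = rep_len(orientation, length(onsets)),
    pulse_type = rep_len(pulse_type, length(onsets)),
    animal_id = rep_len(as.character(animal_id), length(onsets)),
    stringsAsFactors = FALSE)
  class(out) <- c("stimulus_log", "data.frame")
  out
}

#' Spike train
#'
#' @param timestamps spike times in seconds; sorted on construction.
#' @param source_channel channel the spikes were detected on.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(timestamps, source_channel = "ch1") {
  structure(
    list(timestamps = sort(as.numeric(timestamps)),
         source_channel = as.character(source_channel)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes on %s\n",
              length(x$timestamps), x$source_channel))
  invisible(x)
}

#' Convert milliseconds to seconds
#' @param ms time in milliseconds.
#' @return time in seconds.
#' @export
ms_to_s <- function(ms) ms / 1000

#' Convert seconds to milliseconds
#' @param s time in seconds.
#' @return time in milliseconds.
#' @export
s_to_ms <- function(s) s * 1000

.session_fields <- list(
  recording = c("samples", "fs", "start_time", "channel_id",
                "excluded_intervals"),
  stimlog = c("onset", "intensity_pct_mt", "orientation", "pulse_type",
              "animal_id"))

#' Write a recording session to disk
#'
#' Sessions are stored as a single serialized container holding the
#' continuous recording(s), the stimulus log, and optional spike trains,
#' EMG traces and ground-truth tables. The round trip through
#' [read_session()] is lossless (sample-exact, full double precision).
#'
#' @param session a list with at least elements `recording`
#'   (a [continuous_recording()] or list of them) and `stimlog`
#'   (a [stimulus_log()]); extra elements are preserved verbatim.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(is.list(session))
  session$schema_version <- 1L
  saveRDS(session, path)
  invisible(path)
}

#' Read a recording session
#'
#' Validates the container schema: the mandatory recording and stimulus-log
#' fields must be present, and errors name the missing field.
#'
#' @param path file written by [write_session()].
#' @return the session list.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  session <- readRDS(path)
  if (is.null(session$schema_version) || session$schema_version > 1L)
    stop("unsupported session schema version")
  recs <- session$recording
  if (is.null(recs)) stop("session schema error: missing field 'recording'")
  if (inherits(recs, "continuous_recording") ||
      (!is.null(names(recs)) &&
         any(.session_fields$recording %in% names(recs))))
    recs <- list(recs)
  for (r in recs) {
    miss <- setdiff(.session_fields$recording, names(r))
    if (length(miss))
      stop("session schema error: recording missing field '", miss[1L], "'")
  }
  if (is.null(session$stimlog))
    stop("session schema error: missing field 'stimlog'")
  miss <- setdiff(.session_fields$stimlog, names(session$stimlog))
  if (length(miss))
    stop("session schema error: stimlog missing field '", miss[1L], "'")
  session
}

#' Write detected phasic events to CSV
#'
#' One row per event with columns `label`, `polarity`, `onset_ms`,
#' `offset_ms`, `duration_ms`, `peak_time_ms`, `peak_normalized_fr`.
#' An empty event set produces a header-only file.
#'
#' @param events a `phasic_events` data.frame from [detect_phasic()] /
#'   [classify_phases()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("label", "polarity", "onset_ms", "offset_ms", "duration_ms",
            "peak_time_ms", "peak_normalized_fr")
  df <- as.data.frame(events)[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phasic-event CSV written by [write_events_csv()]
#' @param path CSV path.
#' @return a data.frame of events.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("phasic_events", "data.frame")
  df
}
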