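#' Spike-detection configuration
#'
#' Defaults mirror a typical extracellular multiunit chain: a 300 Hz - 5 kHz
#' spike band, a threshold of `k` times the median-based noise SD, and
#' negative-going detection (extracellular somatic spikes are predominantly
#' negative). The dead time approximates a refractory period; the blanking
#' exclusion is padded by `exclusion_pad_ms` before detection so filter
#' ringing at blanking edges cannot be logged as spikes.
#'
#' @param band numeric length-2 passband in Hz, default `c(300, 5000)`.
#' @param k threshold multiplier on the noise SD estimate (3.5 or 4 are the
#'   conventional choices), default 4.
#' @param dead_time_ms suppression window after each detection, ms.
#' @param polarity `"negative"`, `"positive"` or `"both"`.
#' @param order Butterworth order (applied forward-backward).
#' @param exclusion_pad_ms padding added to each excluded interval before
#'   detection, ms.
#' @param sigma optional fixed noise SD in microvolts; if `NULL` it is
#'   estimated from the data with [estimate_noise_sd()].
#' @return a `detection_config` list.
#' @export
detection_config <- function(band = c(300, 5000), k = 4,
                             dead_time_ms = 0.8,
                             polarity = c("negative", "positive", "both"),
                             order = 4, exclusion_pad_ms = 1,
                             sigma = NULL) {
  polarity <- match.arg(polarity)
  if (!is.numeric(band) || length(band) != 2L || band[1L] <= 0 ||
      band[2L] <= band[1L])
    stop("'band' must satisfy 0 < low < high")
  if (k <= 0) stop("'k' must be positive")
  if (dead_time_ms < 0) stop("'dead_time_ms' must be >= 0")
  structure(list(band = band, k = k, dead_time_ms = dead_time_ms,
                 polarity = polarity, order = order,
                 exclusion_pad_ms = exclusion_pad_ms, sigma = sigma),
            class = "detection_config")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters the trace forward and backward (anti-causal application), which
#' squares the magnitude response and cancels the phase response, so spike
#' and event timings are not shifted. Excluded intervals carry over
#' unchanged; output length equals input length.
#'
#' @param rec a [continuous_recording()] or plain numeric vector.
#' @param band passband in Hz.
#' @param fs sampling rate in Hz (taken from `rec` when it is a recording).
#' @param order filter order before the forward-backward pass.
#' @return object of the same type as `rec`, filtered.
#' @export
bandpass <- function(rec, band = c(300, 5000), fs = NULL, order = 4) {
  is_rec <- inherits(rec, "continuous_recording")
  if (is_rec) fs <- rec$fs
  if (is.null(fs)) stop("'fs' required for plain numeric input")
  if (band[2L] >= fs / 2)
    stop("band edge must be below the Nyquist frequency")
  if (band[1L] <= 0) stop("band low edge must be positive")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- if (is_rec) rec$samples else as.numeric(rec)
  y <- as.numeric(signal::filtfilt(bf, x))
  if (!is_rec) return(y)
  out <- rec
  out$samples <- y
  out
}

#' Median-based robust noise SD estimate
#'
#' Estimates the background-noise standard deviation as
#' `median(|x|) / 0.6745`, the Gaussian-consistent median-of-absolutes
#' scale. Unlike the sample SD, this is insensitive to high spike rates or
#' large spike amplitudes contaminating the trace. Samples inside excluded
#' (blanked) intervals are ignored.
#'
#' @param x a [continuous_recording()] or numeric vector of filtered
#'   samples.
#' @param min_samples minimum number of usable samples.
#' @return estimated noise SD in the input's voltage units.
#' @export
estimate_noise_sd <- function(x, min_samples = 1000) {
  if (inherits(x, "continuous_recording")) {
    keep <- !in_intervals(rec_times(x), x$excluded_intervals)
    x <- x$samples[keep]
  }
  x <- as.numeric(x)
  if (length(x) < min_samples)
    stop("too few samples (", length(x), ") for a stable noise estimate")
  stats::median(abs(x)) / 0.6745
}

# membership of times in a set of [t0, t1) intervals
in_intervals <- function(t, intervals) {
  res <- rep(FALSE, length(t))
  for (j in seq_len(nrow(intervals)))
    res <- res | (t >= intervals[j, 1L] & t < intervals[j, 2L])
  res
}

#' Amplitude-threshold multiunit spike detection
#'
#' A spike is logged at each local extremum of the chosen polarity whose
#' magnitude exceeds `k` times the median-based noise SD. After each
#' detection, further crossings within the dead time are suppressed
#' (earliest-first). Extrema inside excluded intervals -- padded by
#' `exclusion_pad_ms` on both sides -- are never logged.
#'
#' The input is expected to be spike-band filtered (see [bandpass()]); the
#' trace is used as given.
#'
#' @param rec a bandpass-filtered [continuous_recording()].
#' @param cfg a [detection_config()].
#' @return a [spike_train()] with timestamps in seconds.
#' @export
detect_spikes <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "continuous_recording"),
            inherits(cfg, "detection_config"))
  sigma <- if (is.null(cfg$sigma)) estimate_noise_sd(rec) else cfg$sigma
  if (sigma <= 0)
    stop("degenerate threshold: noise SD estimate is zero")
  thr <- cfg$k * sigma
  x <- rec$samples
  n <- length(x)
  cand <- integer(0)
  if (n >= 3L) {
    core <- 2:(n - 1L)
    if (cfg$polarity %in% c("negative", "both")) {
      neg <- core[x[core] < -thr & x[core] <= x[core - 1L] &
                    x[core] <= x[core + 1L]]
      cand <- c(cand, neg)
    }
    if (cfg$polarity %in% c("positive", "both")) {
      pos <- core[x[core] > thr & x[core] >= x[core - 1L] &
                    x[core] >= x[core + 1L]]
      cand <- c(cand, pos)
    }
  }
  cand <- sort(unique(cand))
  t_cand <- rec$start_time + (cand - 1L) / rec$fs
  if (nrow(rec$excluded_intervals) > 0L) {
    pad <- cfg$exclusion_pad_ms / 1000
    padded <- cbind(rec$excluded_intervals[, 1L] - pad,
                    rec$excluded_intervals[, 2L] + pad)
    keep <- !in_intervals(t_cand, padded)
    t_cand <- t_cand[keep]
  }
  if (cfg$dead_time_ms > 0 && length(t_cand) > 1L) {
    dead <- cfg$dead_time_ms / 1000
    kept <- numeric(length(t_cand))
    m <- 0L
    last <- -Inf
    for (tt in t_cand) {
      if (tt - last >= dead) {
        m <- m + 1L
        kept[m] <- tt
        last <- tt
      }
    }
    t_cand <- kept[seq_len(m)]
  }
  spike_train(t_cand, source_channel = rec$channel_id)
}
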