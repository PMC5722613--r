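#' Zero-phase EMG bandpass filter
#'
#' 4th-order Butterworth bandpass (default 100-1000 Hz) applied
#' anti-causally (forward-backward), preserving MUAP onset timing.
#'
#' @param trace EMG samples, microvolts.
#' @param fs sampling rate, Hz.
#' @param band passband in Hz.
#' @param order filter order before the forward-backward pass.
#' @return filtered trace.
#' @export
filter_emg <- function(trace, fs, band = c(100, 1000), order = 4) {
  if (band[2L] >= fs / 2) stop("band edge must be below Nyquist")
  if (band[1L] <= 0) stop("band low edge must be positive")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(trace)))
}

#' MUAP onset-latency estimation
#'
#' The onset is the first post-stimulus time (after a short blank skipping
#' residual stimulus artifact) at which the rectified EMG exceeds `k_emg`
#' times the robust (median-based) SD of the rectified pre-stimulus
#' baseline for at least `persist_ms` continuously. The threshold is
#' noise-relative, so the estimate is invariant to amplitude scaling.
#'
#' @param trace filtered EMG trace, microvolts.
#' @param fs sampling rate, Hz.
#' @param stim_onset_s stimulus onset in seconds from trace start; at least
#'   100 ms of baseline must precede it.
#' @param k_emg threshold multiplier, default 3.
#' @param blank_ms post-stimulus blank before the search starts, ms.
#' @param persist_ms required supra-threshold persistence, ms.
#' @param max_latency_ms responses later than this are reported absent.
#' @return a `muap_result` list: `response_present`, `onset_latency_ms`
#'   (NA when absent), `threshold_uv`.
#' @export
detect_muap_onset <- function(trace, fs, stim_onset_s, k_emg = 3,
                              blank_ms = 2, persist_ms = 1,
                              max_latency_ms = 50) {
  trace <- as.numeric(trace)
  onset_idx <- round(stim_onset_s * fs) + 1L
  if (onset_idx - 1L < 0.1 * fs)
    stop("need at least 100 ms of pre-stimulus baseline")
  base <- abs(trace[seq_len(onset_idx - 1L)])
  sd_r <- stats::median(base) / 0.6745
  thr <- k_emg * sd_r
  i0 <- onset_idx + round(blank_ms / 1000 * fs)
  i1 <- min(length(trace), onset_idx + round(max_latency_ms / 1000 * fs))
  res <- list(response_present = FALSE, onset_latency_ms = NA_real_,
              threshold_uv = thr)
  class(res) <- "muap_result"
  if (i0 >= i1) return(res)
  seg <- abs(trace[i0:i1]) > thr
  need <- max(1L, round(persist_ms / 1000 * fs))
  r <- rle(seg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit)) {
    first <- i0 + starts[hit[1L]] - 1L
    res$response_present <- TRUE
    res$onset_latency_ms <- (first - onset_idx) / fs * 1000
  }
  res
}

#' Contra/ipsi laterality ratio of the evoked EMG response
#'
#' Ratio of mean rectified post-stimulus area, contralateral over
#' ipsilateral, computed over the given window for paired trials. A zero
#' ipsilateral area yields an infinite ratio (flagged).
#'
#' @param contra,ipsi numeric vectors or lists of paired trial traces,
#'   microvolts.
#' @param fs sampling rate, Hz.
#' @param stim_onset_s stimulus onset, seconds from trace start.
#' @param window_ms post-stimulus window in ms, default `c(5, 50)`.
#' @return list with `ratio`, `contra_area`, `ipsi_area`,
#'   `ipsi_zero` flag.
#' @export
laterality <- function(contra, ipsi, fs, stim_onset_s,
                       window_ms = c(5, 50)) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  contra <- as_list(contra)
  ipsi <- as_list(ipsi)
  if (length(contra) != length(ipsi))
    stop("contra and ipsi trials must be paired")
  area <- function(x) {
    i0 <- round((stim_onset_s + window_ms[1L] / 1000) * fs) + 1L
    i1 <- min(length(x), round((stim_onset_s + window_ms[2L] / 1000) * fs))
    mean(abs(x[i0:i1]))
  }
  ca <- mean(vapply(contra, area, numeric(1L)))
  ia <- mean(vapply(ipsi, area, numeric(1L)))
  list(ratio = if (ia > 0) ca / ia else Inf,
       contra_area = ca, ipsi_area = ia, ipsi_zero = ia == 0)
}
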