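#' Piecewise-constant peri-stimulus rate profile
#'
#' Encodes the intensity function of an inhomogeneous Poisson process as a
#' constant baseline plus additive box components; negative components model
#' evoked suppression. The effective rate is floored at zero, so a component
#' of `-baseline_rate` silences the process over its span.
#'
#' @param baseline_rate baseline firing rate in events/s (>= 0).
#' @param components data.frame (or NULL) with columns `t_start`, `t_end`
#'   (ms relative to stimulus onset, inside the trial window) and
#'   `additive_rate` (events/s, may be negative).
#' @param window trial window in ms relative to stimulus, default
#'   `c(-500, 1000)`.
#' @return An object of class `rate_profile`.
#' @export
rate_profile <- function(baseline_rate, components = NULL,
                         window = c(-500, 1000)) {
  if (!is.numeric(baseline_rate) || length(baseline_rate) != 1L ||
      baseline_rate < 0)
    stop("'baseline_rate' must be a single non-negative rate")
  if (is.null(components))
    components <- data.frame(t_start = numeric(0), t_end = numeric(0),
                             additive_rate = numeric(0))
  components <- as.data.frame(components)
  stopifnot(all(c("t_start", "t_end", "additive_rate") %in%
                  names(components)))
  if (nrow(components) > 0L) {
    if (any(components$t_end <= components$t_start))
      stop("components must have t_end > t_start")
    if (any(components$t_start < window[1L] | components$t_end > window[2L]))
      stop("components must lie inside the trial window")
  }
  structure(list(baseline_rate = baseline_rate, components = components,
                 window = window),
            class = "rate_profile")
}

#' Evaluate a rate profile
#'
#' @param profile a [rate_profile()].
#' @param t_ms times in ms relative to stimulus onset.
#' @return effective rate lambda(t) in events/s, floored at zero. Components
#'   are active on the half-open span `[t_start, t_end)`.
#' @export
rate_at <- function(profile, t_ms) {
  lam <- rep(profile$baseline_rate, length(t_ms))
  cmp <- profile$components
  for (i in seq_len(nrow(cmp))) {
    act <- t_ms >= cmp$t_start[i] & t_ms < cmp$t_end[i]
    lam[act] <- lam[act] + cmp$additive_rate[i]
  }
  pmax(lam, 0)
}

#' Intensity scaling used by the calibrated presets
#'
#' Maps stimulation intensity (%MT) to a component scale factor: 0 at sham,
#' 1 at 120 %MT, interpolated in between and clamped outside. Monotone by
#' construction, so preset excitations grow and suppression deepens with
#' intensity.
#'
#' @param intensity_pct_mt intensity in percent motor threshold.
#' @return scale factor(s) in `[0, 1]`.
#' @export
intensity_scale <- function(intensity_pct_mt) {
  stats::approx(x = c(0, 95, 100, 120), y = c(0, 0.5, 0.7, 1.0),
                xout = intensity_pct_mt, rule = 2)$y
}

#' Calibrated evoked rate profiles
#'
#' Returns the package's calibrated peri-stimulus profile for a given coil
#' orientation and intensity, mirroring the multiphasic evoked structure of
#' TMS-evoked layer V activity: an intermediate excitation peaking near
#' 20 ms, a long suppression epoch, and a rebound excitation ending by
#' 300 ms; under PA orientation additionally two narrow short-latency bumps
#' at 1-1.5 ms and 2.5-4.5 ms (the I-wave windows), absent under ML.
#'
#' Absolute rates (baseline 15 events/s; component amplitudes below) are
#' documented package constants: published evoked profiles are reported as
#' baseline-normalized firing rate, not absolute rate, so the absolute scale
#' is a package choice.
#'
#' @param orientation `"ML"` or `"PA"`.
#' @param intensity_pct_mt intensity in percent motor threshold; 0 gives a
#'   pure-baseline (sham) profile.
#' @param baseline_rate baseline firing rate, events/s.
#' @return a [rate_profile()].
#' @export
preset_profile <- function(orientation, intensity_pct_mt,
                           baseline_rate = 15) {
  if (!is.character(orientation) || length(orientation) != 1L ||
      !orientation %in% c("ML", "PA"))
    stop("unknown orientation: must be 'ML' or 'PA'")
  s <- intensity_scale(intensity_pct_mt)
  if (s <= 0)
    return(rate_profile(baseline_rate))
  cmp <- data.frame(
    t_start = c(8, 14, 18, 40, 200, 230),
    t_end   = c(32, 26, 22, 180, 300, 270),
    additive_rate = c(20, 40, 30, -baseline_rate, 6, 6) * s)
  if (orientation == "PA") {
    cmp <- rbind(cmp, data.frame(
      t_start = c(1, 2.5),
      t_end   = c(1.5, 4.5),
      additive_rate = c(400, 250) * s))
  }
  rate_profile(baseline_rate, cmp)
}

#' Draw one peri-stimulus spike train
#'
#' Samples an inhomogeneous Poisson process with intensity `rate_at(profile)`
#' by thinning (Lewis-Shedler): candidate events are drawn homogeneously at
#' the profile's maximum rate and retained with probability
#' `lambda(t) / lambda_max`. Exact for piecewise-constant rates.
#'
#' @param profile a [rate_profile()].
#' @param window window in ms relative to stimulus; defaults to the
#'   profile's trial window.
#' @param seed integer seed; the seed fully determines the draw.
#' @return sorted numeric vector of event times in ms relative to stimulus.
#' @export
generate_spike_train <- function(profile, window = profile$window,
                                 seed = NULL) {
  stopifnot(inherits(profile, "rate_profile"))
  if (!is.null(seed)) set.seed(seed)
  pos <- profile$components$additive_rate
  lambda_max <- profile$baseline_rate + sum(pos[pos > 0])
  dur_s <- (window[2L] - window[1L]) / 1000
  if (lambda_max <= 0 || dur_s <= 0) return(numeric(0))
  n_cand <- stats::rpois(1L, lambda_max * dur_s)
  if (n_cand == 0L) return(numeric(0))
  t_cand <- stats::runif(n_cand, window[1L], window[2L])
  keep <- stats::runif(n_cand) < rate_at(profile, t_cand) / lambda_max
  sort(t_cand[keep])
}

#' Session configuration for the synthetic generator
#'
#' @param n_trials number of stimuli.
#' @param intensity_pct_mt stimulation intensity, %MT (recycled per trial).
#' @param orientation `"ML"` or `"PA"`.
#' @param fs sampling rate, Hz.
#' @param noise_sd additive Gaussian noise SD, microvolts.
#' @param spike_waveform waveform template in microvolts sampled at `fs`;
#'   default [default_spike_waveform()].
#' @param blanking_ms amplifier blanking window in ms relative to each
#'   stimulus, default `c(-0.2, 0.8)`.
#' @param isi_s inter-stimulus interval in seconds; must exceed the trial
#'   window length (1.5 s).
#' @param pre_s recording time before the first stimulus, seconds.
#' @param seed integer seed; fully determines all generated data.
#' @param animal_id animal label for the stimulus log.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_trials = 40, intensity_pct_mt = 120,
                         orientation = "ML", fs = 40000, noise_sd = 5,
                         spike_waveform = NULL,
                         blanking_ms = c(-0.2, 0.8), isi_s = 2,
                         pre_s = 0.6, seed = 1L, animal_id = "a1") {
  if (fs <= 0) stop("'fs' must be positive")
  if (isi_s <= 1.5)
    stop("inter-stimulus interval must exceed the 1.5 s trial window")
  if (is.null(spike_waveform)) spike_waveform <- default_spike_waveform(fs)
  structure(list(n_trials = n_trials,
                 intensity_pct_mt = intensity_pct_mt,
                 orientation = orientation, fs = fs, noise_sd = noise_sd,
                 spike_waveform = spike_waveform,
                 blanking_ms = blanking_ms, isi_s = isi_s, pre_s = pre_s,
                 seed = as.integer(seed), animal_id = animal_id),
            class = "synth_config")
}

#' Default extracellular spike waveform
#'
#' Biphasic 1 ms template with a negative leading phase, the typical
#' polarity of extracellular somatic spikes; this makes detection-polarity
#' behaviour directly testable.
#'
#' @param fs sampling rate, Hz.
#' @param amplitude_uv magnitude of the negative trough, microvolts.
#' @return numeric waveform vector at `fs`.
#' @export
default_spike_waveform <- function(fs, amplitude_uv = 60) {
  n <- max(4L, round(fs * 0.001))
  ph <- seq(0, 2 * pi, length.out = n)
  -amplitude_uv * sin(ph) * exp(-((seq_len(n) - 1) / n)^2)
}

#' Render spike trains into a continuous voltage trace
#'
#' Places one copy of the spike waveform at each spike time (overlaps sum
#' linearly), adds i.i.d. Gaussian noise, and zeroes all samples inside the
#' per-stimulus blanking window, emulating the grounded amplifier input.
#' Stimulus onsets are spaced `isi_s` apart starting at `pre_s`.
#'
#' @param trains list of length `n_trials`; each element a numeric vector of
#'   spike times in ms relative to its stimulus.
#' @param cfg a [synth_config()].
#' @return list with elements `recording` (a [continuous_recording()]) and
#'   `stimlog` (a [stimulus_log()]).
#' @export
render_continuous <- function(trains, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$fs <= 0) stop("'fs' must be positive")
  n_trials <- length(trains)
  onsets <- cfg$pre_s + (seq_len(n_trials) - 1L) * cfg$isi_s
  dur <- cfg$pre_s + (n_trials - 1L) * cfg$isi_s + 1.2
  n <- round(dur * cfg$fs)
  set.seed(cfg$seed)
  x <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  wf <- cfg$spike_waveform
  nw <- length(wf)
  for (i in seq_len(n_trials)) {
    for (t_ms in trains[[i]]) {
      i0 <- round((onsets[i] + t_ms / 1000) * cfg$fs) + 1L
      idx <- i0:(i0 + nw - 1L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + wf[ok]
    }
  }
  excl <- cbind(onsets + cfg$blanking_ms[1L] / 1000,
                onsets + cfg$blanking_ms[2L] / 1000)
  for (j in seq_len(nrow(excl))) {
    a <- max(1L, floor(excl[j, 1L] * cfg$fs) + 1L)
    b <- min(n, ceiling(excl[j, 2L] * cfg$fs))
    if (b >= a) x[a:b] <- 0
  }
  rec <- continuous_recording(x, cfg$fs, channel_id = "synth",
                              excluded_intervals = excl)
  sl <- stimulus_log(onsets, cfg$intensity_pct_mt, cfg$orientation,
                     animal_id = cfg$animal_id)
  list(recording = rec, stimlog = sl)
}

#' Simulate a full synthetic session
#'
#' Draws per-trial spike trains from the calibrated profile for the
#' configured orientation/intensity and (optionally) renders them into a
#' continuous trace. Trial `i` uses seed `cfg$seed + i`, so sessions are
#' reproducible per seed and trials are independent.
#'
#' @param cfg a [synth_config()].
#' @param profile optional [rate_profile()] overriding the preset.
#' @param render if `TRUE`, also render the continuous recording (slow for
#'   many trials); if `FALSE`, only spike-level data are produced.
#' @return list with `trains` (ground-truth per-trial spike times, ms),
#'   `profile`, `stimlog`, `spikes` (ground-truth absolute-time
#'   [spike_train()]), and, when rendered, `recording`.
#' @export
simulate_session <- function(cfg, profile = NULL, render = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(profile))
    profile <- preset_profile(cfg$orientation, cfg$intensity_pct_mt)
  trains <- lapply(seq_len(cfg$n_trials), function(i)
    generate_spike_train(profile, seed = cfg$seed + i))
  onsets <- cfg$pre_s + (seq_len(cfg$n_trials) - 1L) * cfg$isi_s
  out <- list(trains = trains, profile = profile,
              stimlog = stimulus_log(onsets, cfg$intensity_pct_mt,
                                     cfg$orientation,
                                     animal_id = cfg$animal_id),
              spikes = spike_train(
                unlist(Map(function(tr, on) on + tr / 1000, trains,
                           onsets)),
                source_channel = "synth"))
  if (render) {
    rc <- render_continuous(trains, cfg)
    out$recording <- rc$recording
    out$stimlog <- rc$stimlog
  }
  out
}

#' Synthesize a low-gain monitoring voltage from an injected current
#'
#' The low-gain monitoring channel reads the voltage across the amplifier
#' input capacitance, so a loop current `I(t)` produces
#' `V(t) = (1/C_in) * integral of I`. This is the exact inverse of
#' [current_from_lgm()] at zero noise (up to discretization).
#'
#' @param current current time-series in amperes, uniformly sampled.
#' @param c_in amplifier input capacitance in farads (> 0).
#' @param fs sampling rate, Hz.
#' @param noise_sd optional additive voltage noise SD, volts.
#' @param seed seed for the noise draw.
#' @return voltage time-series in volts, same length as `current`.
#' @export
generate_lgm_trace <- function(current, c_in, fs, noise_sd = 0,
                               seed = NULL) {
  if (!is.numeric(c_in) || length(c_in) != 1L || c_in <= 0)
    stop("'c_in' must be a single positive capacitance")
  v <- pracma::cumtrapz(seq_along(current) / fs, as.numeric(current))[, 1L] /
    c_in
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  v
}

#' Default motor-unit action potential template
#'
#' A ~6 ms Hann-windowed oscillation (carrier ~420 Hz, inside the
#' 100-1000 Hz EMG band). The envelope rises smoothly from zero, as real
#' MUAPs do; a step onset would splash broadband energy backward through
#' the anti-causal EMG filter and corrupt onset-latency estimates. The
#' first sample is kept slightly above zero so planted onsets remain
#' sample-exact.
#'
#' @param fs sampling rate, Hz.
#' @param amplitude_uv peak amplitude, microvolts.
#' @return numeric waveform vector.
#' @export
default_muap_template <- function(fs, amplitude_uv = 300) {
  n <- max(8L, round(fs * 0.006))
  t <- (seq_len(n) - 1L) / fs
  rise <- 6e-4  # raised-cosine rise time, s
  env <- ifelse(t < rise, sin(pi * t / (2 * rise))^2,
                exp(-(t - rise) / 2e-3))
  w <- amplitude_uv * env * sin(2 * pi * 350 * t)
  w[1L] <- amplitude_uv * 1e-3
  w
}

#' Generate a synthetic stimulus-aligned EMG trial
#'
#' The contralateral trace contains the MUAP template starting `latency_ms`
#' after stimulus onset plus Gaussian noise; the ipsilateral trace is noise
#' only (the evoked response is unilateral).
#'
#' @param latency_ms MUAP onset latency after the stimulus, ms (>= 0).
#' @param muap_template waveform in microvolts at `fs`; default
#'   [default_muap_template()].
#' @param noise_sd Gaussian noise SD, microvolts; the default 30 uV is a
#'   typical in vivo intramuscular noise floor (SNR 10 against the default
#'   300 uV MUAP).
#' @param side `"both"` (default, returns the contra/ipsi pair), `"contra"`
#'   or `"ipsi"` (returns that single trace in `$trace`).
#' @param fs sampling rate, Hz.
#' @param pre_ms baseline duration before the stimulus, ms.
#' @param post_ms duration after the stimulus, ms.
#' @param seed integer seed.
#' @return list with `fs`, `stim_onset_s`, and either `contra`/`ipsi`
#'   traces (microvolts) or a single `trace`.
#' @export
generate_emg <- function(latency_ms = 11, muap_template = NULL,
                         noise_sd = 30, side = c("both", "contra", "ipsi"),
                         fs = 20000, pre_ms = 150, post_ms = 100,
                         seed = NULL) {
  side <- match.arg(side)
  if (latency_ms < 0) stop("'latency_ms' must be >= 0")
  if (is.null(muap_template)) muap_template <- default_muap_template(fs)
  if (!is.null(seed)) set.seed(seed)
  n <- round((pre_ms + post_ms) / 1000 * fs)
  onset_idx <- round(pre_ms / 1000 * fs) + 1L
  mk_noise <- function()
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  plant <- function(x) {
    i0 <- onset_idx + round(latency_ms / 1000 * fs)
    idx <- i0:(i0 + length(muap_template) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + muap_template[ok]
    x
  }
  out <- list(fs = fs, stim_onset_s = pre_ms / 1000)
  if (side == "both") {
    out$contra <- plant(mk_noise())
    out$ipsi <- mk_noise()
  } else if (side == "contra") {
    out$trace <- plant(mk_noise())
  } else {
    out$trace <- mk_noise()
  }
  out
}
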