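#' ICMS charge-injection reference thresholds
#'
#' Bipolar charge-transfer levels (in picocoulombs) at which intracortical
#' microstimulation with TMS-like current waveforms is reported to modulate
#' or activate cortical neurons. Inadvertent charge injected by the
#' recording loop is compared against this range; the comparison reports
#' safety factors and never gates execution.
#' @export
ICMS_THRESHOLD_PC <- c(low = 150, high = 800)

#' Loop current from the low-gain monitoring voltage
#'
#' The monitoring channel reads the voltage across the amplifier input
#' capacitance `C_in`, so the current through it is
#' `I(t) = C_in * dV/dt`. Because the parallel input resistance is of
#' teraohm order, its current draw is negligible and `I(t)` equals the
#' total induction current in the loop. The derivative uses central
#' differences on the interior and one-sided differences at the edges.
#'
#' @param v voltage time-series in volts, uniformly sampled.
#' @param c_in amplifier input capacitance in farads (> 0).
#' @param fs sampling rate in Hz; alternatively pass `t`.
#' @param t optional explicit time axis in seconds; must be uniform.
#' @return current time-series in amperes, same length as `v`.
#' @export
current_from_lgm <- function(v, c_in, fs = NULL, t = NULL) {
  if (!is.numeric(c_in) || length(c_in) != 1L || c_in <= 0)
    stop("'c_in' must be a single positive capacitance")
  v <- as.numeric(v)
  if (is.null(fs)) {
    if (is.null(t)) stop("supply 'fs' or 't'")
    dt <- diff(t)
    if (any(abs(dt - dt[1L]) > 1e-9 * abs(dt[1L])))
      stop("non-uniform sampling")
    fs <- 1 / dt[1L]
  }
  c_in * pracma::gradient(v, h1 = 1 / fs)
}

#' Signed charge transfer and ICMS safety factors
#'
#' Integrates the positive and negative parts of the current separately by
#' the trapezoidal rule over the given window. The bipolar charge transfer
#' `|q_pos| + |q_neg|` is compared against the ICMS modulation/activation
#' range (150-800 pC): `safety_factor_low = 150 pC / q_total`,
#' `safety_factor_high = 800 pC / q_total` (infinite at zero charge).
#'
#' @param current current time-series in amperes.
#' @param fs sampling rate, Hz.
#' @param window_s optional `c(t0, t1)` integration window in seconds from
#'   trace start; default the whole trace.
#' @param c_in capacitance recorded in the report (metadata only).
#' @return a `charge_report` list: `current`, `fs`, `q_pos_pc`,
#'   `q_neg_pc`, `q_total_bipolar_pc`, `peak_current_ua`,
#'   `safety_factor_low`, `safety_factor_high`, `c_in`, `note`.
#' @export
charge_per_phase <- function(current, fs, window_s = NULL, c_in = NA_real_) {
  current <- as.numeric(current)
  t <- (seq_along(current) - 1L) / fs
  if (!is.null(window_s)) {
    sel <- t >= window_s[1L] & t <= window_s[2L]
    if (sum(sel) < 2L) stop("empty integration window")
    t <- t[sel]
    current <- current[sel]
  }
  q_pos <- pracma::trapz(t, pmax(current, 0)) * 1e12
  q_neg <- pracma::trapz(t, pmin(current, 0)) * 1e12
  q_tot <- abs(q_pos) + abs(q_neg)
  structure(list(
    current = current, fs = fs,
    q_pos_pc = q_pos, q_neg_pc = q_neg, q_total_bipolar_pc = q_tot,
    peak_current_ua = max(abs(current)) * 1e6,
    safety_factor_low = if (q_tot > 0) ICMS_THRESHOLD_PC[["low"]] / q_tot
    else Inf,
    safety_factor_high = if (q_tot > 0) ICMS_THRESHOLD_PC[["high"]] / q_tot
    else Inf,
    c_in = c_in,
    note = paste("current through the input resistance neglected",
                 "(teraohm order); I equals the loop induction current")),
    class = "charge_report")
}

#' @export
print.charge_report <- function(x, ...) {
  cat(sprintf(
    "<charge_report> q+ = %.3g pC, q- = %.3g pC, bipolar total = %.3g pC\n",
    x$q_pos_pc, x$q_neg_pc, x$q_total_bipolar_pc))
  cat(sprintf("  peak current %.3g uA; safety factor %.3g-%.3g vs ICMS range\n",
              x$peak_current_ua, x$safety_factor_low, x$safety_factor_high))
  invisible(x)
}

#' Attenuation of a resistive source loaded by a shunt capacitance
#'
#' Models the recording cable's capacitance (together with amplifier input
#' capacitance) as a shunt load on the electrode, taken as a purely
#' resistive source of its impedance magnitude at the probe frequency. The
#' RC voltage divider then attenuates the signal by
#' `1 - 1 / sqrt(1 + (2 pi f R C)^2)`. Monotonically increasing in each
#' argument.
#'
#' @param r_source source (electrode) resistance, ohms.
#' @param c_shunt shunt capacitance, farads.
#' @param f frequency, Hz.
#' @return attenuation as a fraction in `[0, 1)`.
#' @export
rc_divider_attenuation <- function(r_source, c_shunt, f) {
  if (any(r_source < 0) || any(c_shunt < 0) || any(f < 0))
    stop("arguments must be non-negative")
  w <- 2 * pi * f * r_source * c_shunt
  1 - 1 / sqrt(1 + w^2)
}
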