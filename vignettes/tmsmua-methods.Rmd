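---
title: "Methods: quantifying TMS-evoked multiunit activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying TMS-evoked multiunit activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsmua)
```

## The measurement problem

Transcranial magnetic stimulation (TMS) delivered over motor cortex while
recording extracellularly produces, after artifact suppression in
hardware, a voltage trace that is valid everywhere except a short blanking
window around each pulse (default −0.2 to +0.8 ms) during which the
amplifier input is grounded. `tmsmua` quantifies the neuronal response in
such recordings: multiunit spike detection, baseline-normalized
peristimulus firing-rate analysis with an empirical null, phasic-event
detection and classification, intensity regression, and two safety/signal
utilities (inadvertent charge injection, cable attenuation), plus EMG
onset latency for the evoked muscle response.

## Spike detection

The spike band is isolated with a Butterworth bandpass (default
300 Hz–5 kHz, matching a typical TMS-compatible amplifier passband)
applied forward and backward. The anti-causal application cancels the
phase response, so detected spike times are not shifted by the filter; the
cost is that filter energy spreads symmetrically in time, which matters at
blanking edges (below).

The detection threshold is `k` times a robust noise-scale estimate,

σ̂ = median(|x|) / 0.6745,

the Gaussian-consistent median of absolutes. Unlike the sample SD, σ̂ is
nearly unaffected by the spikes themselves, so the threshold does not
inflate with firing rate or spike amplitude. `k` defaults to 4 (3.5 is the
other conventional choice); detection is at local extrema beyond the
threshold. Choices the method leaves open and the package fixes as
documented defaults:

- **Polarity** (`polarity = "negative"`): extracellular somatic spikes are
  predominantly negative-going; configurable to positive or both.
- **Dead time** (`dead_time_ms = 0.8`): suppresses re-triggering within
  roughly a refractory period; earliest-first.
- **Blanking-edge padding** (`exclusion_pad_ms = 1`): synthetic blanking
  zeroes samples, creating discontinuities; after zero-phase filtering
  these ring in both directions, so excluded intervals are padded by about
  one filter impulse-response length before detection. No candidate whose
  extremum falls inside a padded excluded interval is logged.

All detections are pooled into one multiunit cluster. Single-unit
isolation (waveform clustering, drift tracking) is out of scope by design:
the downstream statistics are defined on multiunit firing rate.

## Baseline-normalized PSTH and the empirical percentile null

Each trial spans −500 to +1000 ms around its stimulus, with half-open bins
`[t0, t1)` (1 ms for the long-latency analysis) so no spike is counted
twice at an edge. Counts become instantaneous firing rate (events/s), and
the trial's mean baseline rate (−500 to 0 ms) is subtracted from every bin
of that trial, baseline bins included. This makes the baseline mean
exactly zero per trial by construction — an identity the test suite checks
exactly, not approximately.

Averaging weights animals equally: trials are first averaged within
animal, then per-animal trains are averaged without regard to trial
counts. This matches how population averages over N animals are normally
reported and keeps a high-trial animal from dominating.

The averaged train is smoothed with a Gaussian kernel of σ = 2 ms
(truncated at ±4σ, renormalized to unit sum, reflective boundary — so a
constant train is unchanged and mass is conserved). Significance
thresholds are the 2.5th and 97.5th percentiles of the smoothed train's
own baseline bins, using the linear-interpolation quantile convention
(R type 7), fixed and documented for reproducibility.

Two design points were genuinely open:

- **Band from smoothed or raw values?** The package computes percentiles
  on the same smoothed train used for detection, so the band and the
  trace are commensurate. The alternative (raw-train percentiles) widens
  the band by the smoothing factor (≈ √7 at 1 ms bins) and would make
  moderate suppression — e.g. firing silenced from a 15 events/s baseline,
  a normalized rate of −15 — undetectable in principle, which contradicts
  the fact that inhibition phases of this size are detectable in practice.
- **Which baseline distribution for population figures?** The averaged
  train's own baseline bins (the default here), not bins pooled across
  animals; pooled per-animal bins follow a wider distribution than the
  population average and would miscalibrate the band.

**Calibration caveat.** With a 500 ms baseline at 1 ms bins, the band is
estimated from 500 values whose σ = 2 ms smoothing leaves only ~70
effectively independent samples. Empirical extreme quantiles of a
positively autocorrelated series are biased toward the center, so the band
is slightly narrow and the realized per-bin two-sided error rate exceeds
the nominal 5% by about one percentage point (the acceptance script
measures it on null simulations; removing the smoothing or lengthening the
baseline tenfold restores ≈5% in the same measurement). This
anticonservatism is a property of the percentile-band procedure itself at
this baseline length, not of the implementation; users who need strict
5% control should lengthen the baseline or widen α accordingly.

## Phasic events and phase taxonomy

Per polarity independently, maximal runs of bins beyond the band are
found; runs separated by sub-threshold gaps of at most 10 ms are merged
(tolerating firing jitter); merged runs are kept when their total extent
strictly exceeds 10 ms (≥ 11 bins at 1 ms — "more than 10 ms" is read as
strict, and the gap rule is applied before the duration rule, so two short
runs bridged by a small gap count by their merged extent). Onset and
offset are the outer bin edges; the peak is the extreme bin in the merged
span.

Classification follows the canonical multiphasic taxonomy: an excitation
peaking inside the 1–6 ms short-latency window is `short_latency`; the
first excitation peaking later is `intermediate_excitation` (in the
calibrated synthetic sessions it peaks near 20 ms); the first inhibition
starting after it is `inhibition`; the first excitation after that
inhibition is `rebound_excitation`; everything else stays `unclassified`
(chance crossings of the band do occur, consistent with the calibration
caveat above, and are deliberately left unlabeled rather than suppressed).

The short-latency analysis reuses the identical machinery at 0.5 ms
resolution over the 1–6 ms window, with one deliberate difference: no
temporal smoothing. A σ = 2 ms kernel is wider than the spacing of the
I-wave-window peaks (1–1.5 and 2.5–4.5 ms) and would merge them into one
shoulder; the band is therefore taken on the unsmoothed averaged train and
a single significant 0.5 ms bin counts as an event (`min_dur` of half a
bin, no gap merging).

## Intensity mixed model

Per-trial phase firing rate is regressed on stimulation intensity (%MT,
entered raw — centering changes only the intercept in this design) with a
random intercept per animal:

y_ij = β0 + β·x_ij + u_i + ε_ij, u_i ~ N(0, σ²_a), ε_ij ~ N(0, σ²_e).

The package fits this by restricted maximum likelihood profiled down to
the single variance ratio θ = σ²_a/σ²_e; for fixed θ the generalized
least-squares solution reduces to per-group sufficient statistics (O(G)
per likelihood evaluation), and θ is found by bounded derivative-free
search on log θ over [−30, 15] with tolerance 1e-10 — deterministic and
reproducible, with an explicit boundary comparison at θ = 0 (a zero
group-variance fit is reported, not treated as an error). The test suite
checks the estimates against an independent general-purpose REML
implementation to 1e-6 relative.

Significance of the slope uses a Wald F (numerator df 1) with
**Satterthwaite** denominator df: ddf = 2·Var(β̂)²/Var̂(Var(β̂)), where the
variance of the variance comes from the delta method with the numerical
Hessian of the restricted likelihood in (σ²_a, σ²_e). Exact
Kenward–Roger is not implemented — for this one-random-intercept design
the two approximations differ negligibly while Kenward–Roger costs
considerably more; since the df approximation is the one methodological
substitution in the package it is stated prominently here, the fitted
object records the method, and a parametric-bootstrap F-test
(`test_fixed_effect_boot()`) is provided as an assumption-free
alternative. The test suite verifies the empirical Type-I error of the
default test at the reference design (7 animals × 4 intensities) is
within [0.03, 0.07] at nominal 0.05. A trial-number covariate is
deliberately omitted from the model.

`rank_sum_test()` (used for simple two-group comparisons such as motor
thresholds between coil orientations) computes the exact permutation
distribution of the rank-sum by full enumeration for combined n ≤ 20 —
midranks, so ties are handled exactly — and the tie-corrected normal
approximation beyond that.

## Charge injection and cable attenuation

The low-gain monitoring channel reads the voltage across the amplifier
input capacitance C_in, so the loop current is I(t) = C_in·dV/dt; because
the parallel input resistance is of teraohm order its current draw is
neglected, and I(t) equals the total induction current in the loop. The
derivative uses central differences (one-sided at the edges): local,
robust, and accurate to O(Δt²) on smooth traces — at 40 kHz–1 MHz sampling
of millisecond-scale transients the round trip through the synthetic
monitoring generator recovers currents to better than 1e-3 relative on
interior samples. Across a true current discontinuity the derivative
estimate is wrong at the jump samples themselves; charges, being
integrals, are unaffected at this sampling density.

Positive and negative charge are integrated separately by the trapezoidal
rule; the bipolar total |q⁺| + |q⁻| is compared against the 150–800 pC
range of intracortical-microstimulation modulation/activation thresholds
as two safety factors. The comparison reports; it never gates execution.
C_in has no universal value and is a required user input.

`rc_divider_attenuation()` models the electrode as a purely resistive
source of its impedance magnitude at the probe frequency, loaded by the
cable + amplifier shunt capacitance: attenuation = 1 − 1/√(1 + (2πfRC)²).
The full parallel-RC electrode model is out of scope; the utility answers
the practical question (is cable attenuation acceptable at spike-band
frequencies?) with a closed form that is exact for the stated model and
monotone in every argument.

## EMG

EMG is bandpass filtered (100–1000 Hz, 4th-order Butterworth, anti-causal)
and the MUAP onset is the first post-stimulus time — after a 2 ms blank —
at which rectified EMG exceeds 3× the robust (median-based) SD of the
rectified pre-stimulus baseline for at least 1 ms continuously; absent if
nothing qualifies within 50 ms. The onset criterion is a package
definition (the underlying constants are configurable), and it is
noise-relative, hence invariant to amplitude scaling.

Zero-phase filtering smears a small fraction of MUAP energy backward in
time (the 100 Hz band edge rings over several ms), which puts a floor
under achievable onset precision: with a very low noise floor the
threshold sits below this leak and fires early. At a realistic
intramuscular noise floor (the generator's default, SNR ≈ 10 against a
300 µV MUAP) the estimator is unbiased to within 0.5 ms of the planted
latency, which is what the test suite asserts (bias over 100 seeds, not
per-trial deviation). Laterality is the ratio of mean rectified
post-stimulus area, contralateral over ipsilateral, infinite (flagged)
when the ipsilateral area is zero.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth. It
emulates, per trial, an inhomogeneous Poisson spike process whose
intensity is a constant baseline plus additive box components (floored at
zero — suppression to zero rate is a natural inhibition model, not an
error). Sampling is by Lewis–Shedler thinning against the profile maximum,
exact for piecewise-constant rates. The calibrated presets encode:

- intermediate excitation: stacked boxes over 8–32 ms peaking at
  18–22 ms (+90 events/s at full intensity);
- inhibition: full suppression over 40–180 ms;
- rebound excitation: boxes over 200–300 ms (+12 events/s peak);
- PA orientation only: narrow bumps at 1–1.5 ms (+400 events/s) and
  2.5–4.5 ms (+250 events/s), the I-wave windows; ML plants nothing
  before 6 ms;
- component amplitudes scale monotonically with intensity (0 → sham,
  120 %MT → full), excitations up and suppression deeper.

Baseline rate (15 events/s) and component amplitudes are package
constants: published evoked profiles are baseline-normalized, so absolute
rates are a package choice set to values typical of motor-cortex
multiunit baselines. Rendering to a continuous 40 kHz trace places a
biphasic 1 ms negative-leading waveform at each spike (overlaps sum),
adds white Gaussian noise, zeroes the blanking window, and records the
stimulus log; the EMG generator plants a smoothly rising ~6 ms MUAP
template unilaterally at a configurable latency (default 11 ms); the
monitoring-channel generator is the exact integral inverse of the charge
computation. All outputs are bit-reproducible per seed.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: refractoriness and bursting
(Poisson interval statistics only), electrode drift and amplitude
nonstationarity, correlated or oscillatory background activity, residual
TMS artifact waveforms (induction, polarization decay, vibration — these
are hardware-characterization territory), and biophysical neuron dynamics.
In particular, detection sensitivity on real recordings depends on spike
SNR and background correlation in ways the i.i.d.-noise simulation cannot
certify.

## Problem sizes and numerical conventions

Reference conditions used throughout the package's own validation, chosen
to mirror the reference experiment at desk scale: sessions of 40 trials at
15 events/s baseline; populations of 7 animals (4 for PA short-latency
analyses); 200 null sessions for the Type-I measurement; 100 seeded
populations for planted-phase recovery; 500 simulations for estimator
unbiasedness and 1000 for test calibration. Further conventions: all
stored times are seconds (64-bit float), peri-stimulus quantities are
reported in ms, conversion is centralized; windows and bins are half-open
`[t0, t1)`; the session container is R's native serialization (lossless
round trip), with CSV for event and summary tables and JSON for model
fits and manifests.

## Known limitations

- The percentile band's realized Type-I error runs ≈1 percentage point
  above nominal at the standard baseline length (see the calibration
  caveat); all downstream event detection inherits this.
- Kenward–Roger df are not provided; Satterthwaite (default) or
  parametric bootstrap are.
- The charge computation assumes uniform sampling and a known C_in.
- Multiple-comparison control beyond the per-bin percentile band is out
  of scope, as is single-unit sorting.
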