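# tmsmua

Quantification of TMS-evoked multiunit activity from concurrent
extracellular recordings.

Transcranial magnetic stimulation (TMS) can now be combined with in vivo
extracellular electrophysiology: with a gated amplifier that grounds its
input during a short blanking window around each pulse (−0.2 to +0.8 ms),
spiking activity is recoverable from ~0.8–1 ms after stimulus onset.
`tmsmua` implements the analysis chain that turns such recordings into
quantified evoked responses, and a synthetic-data generator that emulates
the statistical structure of TMS-evoked motor-cortex layer V activity so
the whole chain is testable without animal data.

The pipeline:

1. **Spike detection** — zero-phase Butterworth bandpass (300 Hz–5 kHz),
   robust noise estimation σ̂ = median(|x|)/0.6745, and amplitude
   thresholding at k·σ̂ (k = 3.5 or 4), with detections inside the
   (padded) blanking window excluded. Spikes are pooled into a multiunit
   cluster; no single-unit isolation.
2. **Baseline-normalized PSTH** — trials span −500 to +1000 ms around each
   pulse; per half-open 1 ms bin, instantaneous firing rate (FR) minus the
   trial's mean baseline FR (−500 to 0 ms), so every trial's baseline mean
   is exactly 0. Trials are averaged per animal, then across animals with
   equal weight.
3. **Empirical percentile null** — the 2.5th/97.5th percentiles of the
   smoothed (Gaussian kernel, σ = 2 ms) averaged train's own baseline bins
   form a two-sided p < 0.05 significance band.
4. **Phasic events** — runs of bins beyond the band, merged across
   sub-threshold gaps ≤ 10 ms, kept if longer than 10 ms; classified as
   short-latency (1–6 ms), intermediate excitation (peak ≈ 20 ms),
   inhibition, and rebound excitation. A 0.5 ms-bin variant resolves the
   orientation-dependent short-latency (I-wave window) peaks at 1–1.5 and
   2.5–4.5 ms.
5. **Intensity inference** — per-trial phase FR is modeled as
   `FR ~ intensity(%MT) + (1 | animal)` by the package's own profiled-REML
   random-intercept fit, with a Satterthwaite-df Wald F-test of the slope.
6. **Charge safety** — loop current from the low-gain monitoring voltage,
   `I = C_in · dV/dt` (input-resistance current negligible at teraohm
   scale), integrated into signed charge per phase and compared with the
   150–800 pC intracortical-microstimulation thresholds. A small RC
   voltage-divider utility bounds recording-cable attenuation.
7. **EMG** — 100–1000 Hz anti-causal Butterworth filtering, MUAP
   onset-latency estimation (threshold 3× robust baseline SD, ≥ 1 ms
   persistence), and contra/ipsi laterality.

## Worked example

Simulate the reference experiment — 7 animals, 40 trials at each of 0, 95,
100, 120 %MT, medial–lateral (ML) induced current — and run the full
chain:

```r
library(tmsmua)
cfg <- run_config(out_dir = "demo", seed = 1, n_animals = 7,
                  n_trials = 40, intensities = c(0, 95, 100, 120),
                  orientation = "ML")
res <- run_pipeline(cfg)
res$events
```

```
    polarity onset_ms offset_ms duration_ms peak_time_ms peak_normalized_fr                   label
1 excitation        6        33          27         21.5          88.115321 intermediate_excitation
2 inhibition       39       182         143         48.5         -14.635714              inhibition
3 excitation      220       298          78        247.5          23.532590      rebound_excitation
4 excitation      442       457          15        445.5           9.880807            unclassified
5 excitation      469       488          19        485.5           9.439550            unclassified
```

The three canonical phases of the planted multiphasic response are
recovered (intermediate excitation peaking at 21.5 ms with a normalized FR
of +88 events/s, a long inhibition to −14.6 events/s, rebound excitation
ending by 300 ms). The two late unclassified events are chance crossings
of the empirical band — the method's per-bin false-positive rate is
slightly above nominal (see the methods vignette). The mixed-model stage
prints, per phase:

```
intermediate_excitation: beta = 0.31 +/- 0.02, F(1, 1118) = 166.06, p = 1.58e-35
inhibition:              beta = -0.12 +/- 0.01, F(1, 1118) = 414.46, p = 1.28e-78
rebound_excitation:      beta = 0.07 +/- 0.01, F(1, 1112) = 38.52, p = 7.62e-10
```

i.e. stimulation intensity modulates the two excitation phases positively
and the inhibition phase negatively (slope units: events/s per %MT; the
magnitudes reflect the synthetic generator's calibrated amplitudes, the
sign pattern is the scientifically meaningful recovery). The EMG stage
reports a median MUAP onset latency of 11.20 ms against a planted 11 ms.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/tmsmua`:

```sh
Rscript inst/scripts/tmsmua simulate --orientation PA --intensity 120 \
        --trials 40 --seed 7 --out session.rds
Rscript inst/scripts/tmsmua run --out-dir results --seed 1
```

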