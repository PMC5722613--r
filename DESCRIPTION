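Package: tmsmua
Title: Quantification of TMS-Evoked Multiunit Activity from Concurrent
    Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying neuronal responses evoked
    by transcranial magnetic stimulation (TMS) in concurrent extracellular
    recordings. Provides robust (median-based) multiunit spike detection with
    stimulus-blanking exclusion, baseline-normalized peristimulus time
    histograms with an empirical percentile null band, detection and
    classification of phasic excitation and inhibition epochs, random-intercept
    linear mixed-model regression of phase firing rate on stimulation
    intensity, computation of inadvertent charge injection from low-gain
    monitoring voltages with comparison against intracortical microstimulation
    safety thresholds, and EMG motor-unit-action-potential onset-latency
    analysis. A synthetic-data module generates inhomogeneous-Poisson sessions
    with the evoked structure the analysis assumes, so every stage is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest,
    optparse
Config/testthat/edition: 3
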