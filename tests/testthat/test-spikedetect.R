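test_that("zero-phase bandpass preserves in-band tones and removes DC", {
  fs <- 40000
  t <- seq(0, 0.5, by = 1 / fs)
  x <- sin(2 * pi * 1000 * t)
  y <- bandpass(x, c(300, 5000), fs = fs)
  core <- seq(round(0.1 * fs), round(0.4 * fs))
  # amplitude preserved within 1% ...
  expect_equal(max(abs(y[core])), 1, tolerance = 0.01)
  # ... with zero phase shift (cross-correlation peaks at lag 0)
  cc <- stats::ccf(x[core], y[core], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # DC offset is rejected by the high-pass edge
  expect_lt(abs(mean(bandpass(rep(2, fs), c(300, 5000), fs = fs))), 0.01)
  # all-zero input stays zero
  expect_true(all(bandpass(numeric(1000), c(300, 5000), fs = fs) == 0))
  expect_error(bandpass(x, c(300, 30000), fs = fs), "Nyquist")
})

test_that("bandpass on a recording keeps geometry and exclusions", {
  rec <- continuous_recording(rnorm(40000), 40000,
                              excluded_intervals = rbind(c(0.1, 0.101)))
  out <- bandpass(rec)
  expect_s3_class(out, "continuous_recording")
  expect_length(out$samples, length(rec$samples))
  expect_identical(out$excluded_intervals, rec$excluded_intervals)
})

test_that("median-based noise estimate is accurate and spike-robust", {
  set.seed(101)
  x <- rnorm(400000)
  expect_equal(estimate_noise_sd(x), 1, tolerance = 0.01)
  expect_equal(estimate_noise_sd(numeric(1000)), 0)
  expect_error(estimate_noise_sd(rnorm(10)), "too few samples")
  # 50 spikes/s of 20 uV on 10 s of sigma = 1 noise: robust estimate holds
  # within 5% while the plain SD is inflated past 1.5
  fs <- 40000
  set.seed(202)
  y <- rnorm(10 * fs)
  spike_idx <- sort(sample(length(y) - 10, 500))
  wf <- 20 * sin(2 * pi * (1:8) / 8)  # brief 0.2 ms biphasic deflection
  for (i in spike_idx) y[i:(i + 7L)] <- y[i:(i + 7L)] + wf
  expect_equal(estimate_noise_sd(y), 1, tolerance = 0.05)
  expect_gt(sd(y), 1.5)
})

test_that("noise estimation skips excluded samples", {
  fs <- 1000
  x <- rnorm(5000)
  x[1001:2000] <- 1000  # contaminated span, marked excluded
  rec <- continuous_recording(x, fs, excluded_intervals = rbind(c(1, 2)))
  expect_equal(estimate_noise_sd(rec), 1, tolerance = 0.1)
})

test_that("threshold detection matches a brute-force crossing scan", {
  x <- c(0, -1, -5, -1, 0, -5, 0)
  rec <- continuous_recording(x, 1000)
  cfg <- detection_config(k = 3.5, dead_time_ms = 0, sigma = 1,
                          exclusion_pad_ms = 0)
  got <- detect_spikes(rec, cfg)$timestamps
  expect_equal(got, oracle_detect(x, 1000, 3.5))
  expect_equal(got, c(0.002, 0.005))
  # dead time suppresses the second crossing
  cfg4 <- detection_config(k = 3.5, dead_time_ms = 4, sigma = 1,
                           exclusion_pad_ms = 0)
  got4 <- detect_spikes(rec, cfg4)$timestamps
  expect_equal(got4, oracle_detect(x, 1000, 3.5, dead_time_ms = 4))
  expect_equal(got4, 0.002)
})

test_that("detection equals the oracle on noisy traces for all polarities", {
  set.seed(33)
  fs <- 10000
  x <- rnorm(fs)
  rec <- continuous_recording(x, fs)
  for (pol in c("negative", "positive", "both")) {
    for (dt in c(0, 1.5)) {
      cfg <- detection_config(k = 2.5, dead_time_ms = dt, sigma = 1,
                              polarity = pol, exclusion_pad_ms = 0)
      expect_equal(detect_spikes(rec, cfg)$timestamps,
                   oracle_detect(x, fs, 2.5, pol, dt),
                   info = paste(pol, dt))
    }
  }
})

test_that("extrema inside (padded) excluded intervals are never logged", {
  fs <- 40000
  cfg <- synth_config(n_trials = 3, noise_sd = 2, seed = 6)
  # one spike planted in the blanking window of each trial, one outside
  trains <- rep(list(c(0.1, 200)), 3)
  rc <- render_continuous(trains, cfg)
  filt <- bandpass(rc$recording)
  det <- detect_spikes(filt, detection_config(sigma = 2, k = 4))
  rel <- sapply(det$timestamps, function(ts)
    min(abs(ts - rc$stimlog$onset)) * 1000)
  expect_true(all(rel > 0.8))           # nothing from inside the blank
  near200 <- sapply(rc$stimlog$onset, function(on)
    any(abs(det$timestamps - on - 0.2) < 0.005))
  expect_true(all(near200))             # the planted spikes are found
})

test_that("detection count is non-increasing in the threshold multiplier", {
  set.seed(55)
  rec <- continuous_recording(rnorm(40000), 40000)
  counts <- vapply(c(2, 2.5, 3, 3.5, 4, 5), function(k)
    length(detect_spikes(rec, detection_config(k = k, sigma = 1,
                                               dead_time_ms = 0))$timestamps),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is translation-equivariant away from edges", {
  set.seed(77)
  fs <- 10000
  x <- rnorm(fs)
  shift <- 100L
  x2 <- c(numeric(shift), x)
  cfg <- detection_config(k = 3, sigma = 1, dead_time_ms = 0,
                          exclusion_pad_ms = 0)
  t1 <- detect_spikes(continuous_recording(x, fs), cfg)$timestamps
  t2 <- detect_spikes(continuous_recording(x2, fs), cfg)$timestamps
  t2 <- t2[t2 >= shift / fs]
  expect_equal(t2, t1 + shift / fs)
})

test_that("high-SNR synthetic spikes are recovered near-perfectly", {
  # waveform trough 8x the noise SD, k = 4: sensitivity >= 99%, false
  # positives <= 1/s
  fs <- 40000
  cfg <- synth_config(n_trials = 8, noise_sd = 7.5, seed = 21)
  prof <- rate_profile(15)
  trains <- lapply(1:8, function(i) generate_spike_train(prof,
                                                         seed = 210 + i))
  rc <- render_continuous(trains, cfg)
  filt <- bandpass(rc$recording)
  det <- detect_spikes(filt, detection_config(k = 4))
  truth <- sort(unlist(Map(function(tr, on) on + tr / 1000, trains,
                           rc$stimlog$onset)))
  # trough of the rendered waveform trails the placement time slightly
  matched <- vapply(truth, function(ts)
    any(det$timestamps >= ts - 0.0002 & det$timestamps <= ts + 0.0012),
    logical(1))
  expect_gte(mean(matched), 0.99)
  fp <- sum(vapply(det$timestamps, function(ts)
    !any(abs(truth - ts) < 0.0012), logical(1)))
  expect_lte(fp / rec_duration(rc$recording), 1)
})

test_that("degenerate all-zero traces refuse thresholding", {
  rec <- continuous_recording(numeric(5000), 1000)
  expect_error(detect_spikes(rec, detection_config()), "degenerate")
})
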