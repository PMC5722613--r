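mk_psth <- function(values, bin_size_ms = 1, window_ms = NULL,
                    baseline_frac = 1 / 3) {
  n <- length(values)
  if (is.null(window_ms))
    window_ms <- c(-n * bin_size_ms * baseline_frac,
                   n * bin_size_ms * (1 - baseline_frac))
  edges <- seq(window_ms[1], window_ms[2], by = bin_size_ms)
  structure(list(values = values, centers_ms = edges[-1] - bin_size_ms / 2,
                 edges_ms = edges, bin_size_ms = bin_size_ms,
                 window_ms = window_ms,
                 baseline_window_ms = c(window_ms[1], 0),
                 baseline_bins = which(edges[-1] <= 0 + 1e-9),
                 meta = list(), n_trials = 1, n_animals = 1),
            class = "psth")
}

mk_band <- function(lower, upper) {
  structure(list(lower = lower, upper = upper, n_baseline_samples = 100,
                 alpha = 0.05), class = "significance_band")
}

test_that("binning normalizes every trial's baseline mean to exactly zero", {
  cfg <- synth_config(n_trials = 12, seed = 5)
  ses <- simulate_session(cfg)
  bt <- bin_and_normalize(ses$spikes, ses$stimlog)
  expect_equal(dim(bt$matrix), c(12, 1500))
  base_means <- rowMeans(bt$matrix[, bt$baseline_bins])
  expect_true(all(abs(base_means) < 1e-10))
  # empty train -> every bin zero
  bt0 <- bin_and_normalize(spike_train(numeric(0)), ses$stimlog)
  expect_true(all(bt0$matrix == 0))
})

test_that("a 3-spike bin with empty baseline maps to 3000 events/s", {
  sl <- stimulus_log(10, 120)
  # three spikes inside the bin [100, 101) ms post-stimulus
  sp <- spike_train(10 + c(0.1001, 0.1004, 0.1008))
  bt <- bin_and_normalize(sp, sl)
  target_bin <- which(bt$edges_ms[-length(bt$edges_ms)] == 100)
  expect_equal(bt$matrix[1, target_bin], 3000)
  expect_true(all(bt$matrix[1, -target_bin] == 0))
})

test_that("trials whose window overruns the recording are dropped", {
  rec <- continuous_recording(numeric(80000), 40000)  # 2 s record
  sl <- stimulus_log(c(0.6, 1.5), 120)  # second trial needs data to 2.5 s
  expect_warning(
    bt <- bin_and_normalize(spike_train(numeric(0)), sl, recording = rec),
    "dropped")
  expect_equal(nrow(bt$matrix), 1)
})

test_that("trial averaging weights animals equally", {
  sl <- stimulus_log(c(10, 20, 30), 120,
                     animal_id = c("a1", "a1", "a2"))
  sp <- spike_train(c(10.0505, 20.0505, 20.0515, 30.0505))
  bt <- bin_and_normalize(sp, sl)
  avg <- average_trials(bt, group_by = character(0))[[1]]
  # per-animal means first: a1 = mean(trial1, trial2), a2 = trial3;
  # population = mean of the two per-animal trains
  manual <- (colMeans(bt$matrix[1:2, ]) + bt$matrix[3, ]) / 2
  expect_equal(avg$values, manual)
  expect_equal(avg$n_animals, 2)
  # identical trials average to any one trial
  bt2 <- bt
  bt2$matrix <- rbind(bt$matrix[1, ], bt$matrix[1, ], bt$matrix[1, ])
  expect_equal(average_trials(bt2, character(0))[[1]]$values,
               bt$matrix[1, ])
  # symmetric +a/-a trials cancel
  bt3 <- bt
  bt3$matrix <- rbind(bt$matrix[1, ], -bt$matrix[1, ])
  bt3$trial_meta <- bt$trial_meta[1:2, ]
  bt3$trial_meta$animal_id <- "a1"
  expect_true(all(average_trials(bt3, character(0))[[1]]$values == 0))
})

test_that("grouped averages split by intensity", {
  sl <- stimulus_log(c(10, 20), c(95, 120))
  sp <- spike_train(10.100)
  bt <- bin_and_normalize(sp, sl)
  avgs <- average_trials(bt, group_by = "intensity")
  expect_length(avgs, 2)
  expect_setequal(vapply(avgs, function(a) a$meta$intensity, numeric(1)),
                  c(95, 120))
})

test_that("percentile band follows the linear-interpolation convention", {
  b <- significance_band(1:100)
  expect_equal(b$lower, 3.475)
  expect_equal(b$upper, 97.525)
  # constant (post-normalization zero) baseline collapses the band
  b0 <- significance_band(numeric(50))
  expect_equal(c(b0$lower, b0$upper), c(0, 0))
  expect_error(significance_band(numeric(0)), "no baseline bins")
  expect_warning(significance_band(1:10), "unstable")
})

test_that("Gaussian smoothing conserves mass and leaves constants alone", {
  expect_equal(smooth_train(rep(2.5, 100), 2, 1), rep(2.5, 100))
  imp <- c(numeric(50), 1, numeric(50))
  sm <- smooth_train(imp, 2, 1)
  expect_equal(sum(sm), 1)
  expect_equal(which.max(sm), 51)
  # direct-convolution oracle on a planted 15 ms square bump
  x <- numeric(200); x[100:114] <- 10
  r <- 8
  kern <- dnorm(-r:r, sd = 2); kern <- kern / sum(kern)
  pad <- c(x[r:1], x, x[200:(200 - r + 1)])
  oracle <- vapply(seq_along(x), function(i)
    sum(pad[i:(i + 2 * r)] * rev(kern)), numeric(1))
  expect_equal(smooth_train(x, 2, 1), oracle, tolerance = 1e-12)
  expect_equal(which.max(smooth_train(x, 2, 1)), 107)  # peak not displaced
})

test_that("phasic detection applies the run, gap and duration rules", {
  base <- numeric(60)
  band <- mk_band(-1, 1)
  # never beyond the band -> nothing
  p0 <- mk_psth(c(numeric(30), base), baseline_frac = 1 / 3)
  expect_equal(nrow(detect_phasic(p0, band)), 0)
  # 15 ms continuous run -> one excitation with edge-exact bounds
  v <- base; v[11:25] <- 5
  p <- mk_psth(c(numeric(30), v), baseline_frac = 1 / 3)
  ev <- detect_phasic(p, band)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$polarity, "excitation")
  expect_equal(ev$onset_ms, 10)
  expect_equal(ev$offset_ms, 25)
  expect_equal(ev$duration_ms, 15)
  # two 8 ms runs, 8 ms apart -> merged into one 24 ms event
  v <- base; v[c(1:8, 17:24)] <- 5
  p <- mk_psth(c(numeric(30), v), baseline_frac = 1 / 3)
  ev <- detect_phasic(p, band)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ms, 24)
  # same runs 12 ms apart -> each run is only 8 ms, no event survives
  v <- base; v[c(1:8, 21:28)] <- 5
  p <- mk_psth(c(numeric(30), v), baseline_frac = 1 / 3)
  expect_equal(nrow(detect_phasic(p, band)), 0)
  # a 10 ms run does not satisfy the strict duration rule; 11 ms does
  v <- base; v[1:10] <- 5
  expect_equal(nrow(detect_phasic(mk_psth(c(numeric(30), v),
                                          baseline_frac = 1 / 3), band)), 0)
  v <- base; v[1:11] <- 5
  expect_equal(nrow(detect_phasic(mk_psth(c(numeric(30), v),
                                          baseline_frac = 1 / 3), band)), 1)
  expect_error(detect_phasic(p, band, min_dur_ms = 0), "positive")
})

test_that("phasic detection agrees with the brute-force oracle", {
  set.seed(404)
  band <- mk_band(-2, 2)
  for (rep in 1:30) {
    v <- rnorm(90, sd = 2)
    p <- mk_psth(c(numeric(30), v), baseline_frac = 1 / 4)
    ev <- detect_phasic(p, band, min_dur_ms = 3, max_gap_ms = 2)
    sel <- p$centers_ms > 0
    oracle <- oracle_phasic(p$values[sel],
                            p$edges_ms[-length(p$edges_ms)][sel],
                            p$edges_ms[-1][sel], 2, -2, 3, 2)
    ev <- ev[order(ev$polarity, ev$onset_ms), ]
    okey <- sapply(oracle, function(e)
      paste(e$polarity, e$onset, e$offset))
    ikey <- paste(ev$polarity, ev$onset_ms, ev$offset_ms)
    expect_setequal(ikey, okey)
  }
})

test_that("detection is invariant to a common offset of train and band", {
  set.seed(505)
  v <- rnorm(90, sd = 2)
  p <- mk_psth(c(numeric(30), v), baseline_frac = 1 / 4)
  ev1 <- detect_phasic(p, mk_band(-2, 2), min_dur_ms = 3, max_gap_ms = 2)
  p2 <- p; p2$values <- p$values + 7
  ev2 <- detect_phasic(p2, mk_band(-2 + 7, 2 + 7), min_dur_ms = 3,
                       max_gap_ms = 2)
  expect_equal(ev1$onset_ms, ev2$onset_ms)
  expect_equal(ev1$offset_ms, ev2$offset_ms)
  expect_equal(ev1$polarity, ev2$polarity)
})

test_that("phase classification follows the canonical taxonomy", {
  ev <- data.frame(
    polarity = c("excitation", "inhibition", "excitation"),
    onset_ms = c(10, 50, 180), offset_ms = c(32, 150, 250),
    duration_ms = c(22, 100, 70), peak_time_ms = c(20, 90, 210),
    peak_normalized_fr = c(60, -14, 12), label = "unclassified",
    stringsAsFactors = FALSE)
  got <- classify_phases(ev)
  expect_equal(got$label, c("intermediate_excitation", "inhibition",
                            "rebound_excitation"))
  # a lone excitation peaking at 3 ms is short-latency
  one <- ev[1, ]; one$peak_time_ms <- 3; one$onset_ms <- 1
  expect_equal(classify_phases(one)$label, "short_latency")
  # empty input stays empty
  expect_equal(nrow(classify_phases(ev[0, ])), 0)
})

test_that("per-trial phase extraction matches hand arithmetic", {
  sl <- stimulus_log(c(10, 20, 30), c(95, 100, 120))
  bt <- bin_and_normalize(spike_train(numeric(0)), sl)
  # hand-built 3-trial matrix: bins at 10-13 ms hold known values
  bins <- which(bt$edges_ms[-length(bt$edges_ms)] %in% c(10, 11, 12))
  bt$matrix[1, bins] <- c(1, 2, 3)
  bt$matrix[2, bins] <- c(4, 5, 6)
  bt$matrix[3, bins] <- c(7, 8, 9)
  ev <- data.frame(polarity = "excitation", onset_ms = 10, offset_ms = 13,
                   duration_ms = 3, peak_time_ms = 11.5,
                   peak_normalized_fr = 9,
                   label = "intermediate_excitation",
                   stringsAsFactors = FALSE)
  tab <- extract_phase_fr(bt, ev)
  expect_equal(tab$mean_fr, c(2, 5, 8))
  expect_equal(tab$intensity_pct_mt, c(95, 100, 120))
  # all-zero trials give zero for every phase; single-bin phase returns
  # the bin value
  ev1 <- ev; ev1$onset_ms <- 50; ev1$offset_ms <- 51
  expect_true(all(extract_phase_fr(bt, ev1)$mean_fr == 0))
})

test_that("planted multiphasic structure is recovered end to end", {
  bt <- sim_population_bt(seed = 3100)
  ana <- evoked_analysis(bt)
  labs <- ana$events$label
  expect_true(all(c("intermediate_excitation", "inhibition",
                    "rebound_excitation") %in% labs))
  pk <- ana$events$peak_time_ms[labs == "intermediate_excitation"]
  expect_gte(pk, 15)
  expect_lte(pk, 25)
  inh <- ana$events[ana$events$label == "inhibition", ]
  expect_gt(inh$offset_ms, 100)
  # the intensity trend of the planted profile survives extraction
  tab <- extract_phase_fr(bt, ana$events)
  im <- tab[tab$phase == "intermediate_excitation", ]
  expect_gt(mean(im$mean_fr), 0)
})

test_that("short-latency analysis separates PA from ML", {
  bt_pa <- sim_population_bt(seed = 4200, orientation = "PA",
                             n_animals = 4, bin_size_ms = 0.5)
  sla <- short_latency_analysis(bt_pa)
  ev <- sla$events[sla$events$polarity == "excitation", ]
  covers <- function(ev, w)
    any(ev$onset_ms < w[2] + 1e-9 & ev$offset_ms > w[1] - 1e-9)
  expect_true(covers(ev, c(1, 1.5)))
  expect_true(covers(ev, c(2.5, 4.5)))
  # ML at the same seed shows at most chance-level isolated crossings
  bt_ml <- sim_population_bt(seed = 4200, orientation = "ML",
                             n_animals = 4, bin_size_ms = 0.5)
  sla_ml <- short_latency_analysis(bt_ml)
  ev_ml <- sla_ml$events[sla_ml$events$polarity == "excitation", ]
  expect_lte(nrow(ev_ml), 1)
  expect_true(all(ev_ml$duration_ms <= 0.5 + 1e-9))
})
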