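# Independent brute-force oracles and fixture builders shared across tests.
# The oracles deliberately use naive loops so they cannot share a defect
# with the vectorized implementations they check.

# every sample that is a local extremum beyond the threshold, scanned one
# sample at a time; dead-time suppression applied earliest-first
oracle_detect <- function(x, fs, thr, polarity = "negative",
                          dead_time_ms = 0) {
  hits <- c()
  for (i in 2:(length(x) - 1L)) {
    is_min <- x[i] < -thr && x[i] <= x[i - 1L] && x[i] <= x[i + 1L]
    is_max <- x[i] > thr && x[i] >= x[i - 1L] && x[i] >= x[i + 1L]
    ok <- switch(polarity,
                 negative = is_min, positive = is_max,
                 both = is_min || is_max)
    if (ok) hits <- c(hits, (i - 1L) / fs)
  }
  if (dead_time_ms > 0 && length(hits) > 1L) {
    out <- hits[1L]
    for (h in hits[-1L])
      if (h - out[length(out)] >= dead_time_ms / 1000) out <- c(out, h)
    hits <- out
  }
  hits
}

# run/merge/duration rule by explicit scanning: collect supra-threshold
# runs, then repeatedly merge the closest same-polarity pair while the gap
# is tolerable, then drop short events
oracle_phasic <- function(values, starts, ends, upper, lower,
                          min_dur, max_gap) {
  events <- list()
  for (pol in c("excitation", "inhibition")) {
    flag <- if (pol == "excitation") values > upper else values < lower
    runs <- list()
    i <- 1L
    while (i <= length(flag)) {
      if (flag[i]) {
        j <- i
        while (j < length(flag) && flag[j + 1L]) j <- j + 1L
        runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    repeat {
      if (length(runs) < 2L) break
      merged_any <- FALSE
      for (k in seq_len(length(runs) - 1L)) {
        gap <- starts[runs[[k + 1L]][1L]] - ends[runs[[k]][2L]]
        if (gap <= max_gap + 1e-9) {
          runs[[k]] <- c(runs[[k]][1L], runs[[k + 1L]][2L])
          runs[[k + 1L]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (!merged_any) break
    }
    for (r in runs) {
      dur <- ends[r[2L]] - starts[r[1L]]
      if (dur > min_dur + 1e-9)
        events[[length(events) + 1L]] <-
          list(polarity = pol, onset = starts[r[1L]], offset = ends[r[2L]])
    }
  }
  events
}

# combined binned-trials object for a multi-animal synthetic population
sim_population_bt <- function(seed, orientation = "ML", intensity = 120,
                              n_animals = 7, n_trials = 40,
                              bin_size_ms = 1) {
  bts <- lapply(seq_len(n_animals), function(a) {
    cfg <- synth_config(n_trials = n_trials, intensity_pct_mt = intensity,
                        orientation = orientation,
                        seed = seed + 1000L * a,
                        animal_id = sprintf("a%d", a))
    ses <- simulate_session(cfg)
    bin_and_normalize(ses$spikes, ses$stimlog, bin_size_ms)
  })
  combine_binned(bts)
}

# one no-stimulus-effect session: homogeneous Poisson firing at 15/s,
# returns the fraction of smoothed post-stimulus bins outside the band
null_session_fraction <- function(seed, rate = 15, n_trials = 40) {
  prof <- rate_profile(rate)
  trains <- lapply(seq_len(n_trials), function(i)
    generate_spike_train(prof, seed = seed * 1000L + i))
  onsets <- 0.6 + (seq_len(n_trials) - 1L) * 2
  sp <- spike_train(unlist(Map(function(tr, on) on + tr / 1000,
                               trains, onsets)))
  bt <- bin_and_normalize(sp, stimulus_log(onsets, 0))
  sm <- smooth_train(average_trials(bt, character(0))[[1L]])
  band <- significance_band(sm)
  post <- sm$values[sm$centers_ms > 0]
  mean(post > band$upper | post < band$lower)
}

# balanced mixed-model dataset with a known slope
sim_lmm_data <- function(seed, beta = 2, G = 7, per = 40, va = 4,
                         ve = 25, intercept = 1) {
  set.seed(seed)
  g <- rep(sprintf("a%d", seq_len(G)), each = per)
  x <- rep(rep(c(0, 95, 100, 120), length.out = per), G)
  u <- stats::rnorm(G, 0, sqrt(va))
  y <- intercept + beta * x + u[as.integer(factor(g))] +
    stats::rnorm(length(g), 0, sqrt(ve))
  data.frame(animal_id = g, intensity_pct_mt = x, mean_fr = y,
             stringsAsFactors = FALSE)
}

# two-sided exact rank-sum p by full enumeration (independent of the
# implementation's combn path: explicit recursive subset walk)
oracle_ranksum_p <- function(a, b) {
  m <- length(a)
  rk <- rank(c(a, b))
  ew <- m * (m + length(b) + 1) / 2
  w_obs <- sum(rk[seq_len(m)])
  total <- 0L
  hits <- 0L
  idx <- seq_along(rk)
  subsets <- function(pool, k) {
    if (k == 0L) return(list(integer(0)))
    if (length(pool) < k) return(list())
    with_first <- lapply(subsets(pool[-1L], k - 1L),
                         function(s) c(pool[1L], s))
    c(with_first, subsets(pool[-1L], k))
  }
  for (s in subsets(idx, m)) {
    total <- total + 1L
    if (abs(sum(rk[s]) - ew) >= abs(w_obs - ew) - 1e-9) hits <- hits + 1L
  }
  hits / total
}
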