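#' Pipeline run configuration
#'
#' All stage parameters and toggles for [run_pipeline()], fully
#' serializable so a run's manifest reproduces its outputs.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stochastic stage derives its seeds from
#'   it.
#' @param n_animals animals to simulate.
#' @param n_trials trials per animal per intensity.
#' @param intensities stimulation intensities, %MT.
#' @param orientation `"ML"` or `"PA"`.
#' @param render simulate and detect from the continuous 40 kHz trace
#'   (slow); when `FALSE`, ground-truth spike trains feed the analysis
#'   directly.
#' @param band,k,dead_time_ms spike-detection parameters (used when
#'   `render = TRUE`).
#' @param bin_size_ms,window_ms PSTH geometry.
#' @param sigma_ms,min_dur_ms,max_gap_ms event-detection parameters.
#' @param short_latency run the 0.5 ms-bin short-latency analysis too.
#' @param c_in amplifier input capacitance for the charge stage, farads.
#' @param emg_latency_ms planted EMG latency for the EMG stage.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "psth", "events", "lmm", "charge", "emg")`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("tmsmua_run_"), seed = 1L,
                       n_animals = 7, n_trials = 40,
                       intensities = c(0, 95, 100, 120),
                       orientation = "ML", render = FALSE,
                       band = c(300, 5000), k = 4, dead_time_ms = 0.8,
                       bin_size_ms = 1, window_ms = c(-500, 1000),
                       sigma_ms = 2, min_dur_ms = 10, max_gap_ms = 10,
                       short_latency = orientation == "PA",
                       c_in = 10e-12, emg_latency_ms = 11,
                       stages = c("simulate", "psth", "events", "lmm",
                                  "charge", "emg")) {
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(stage, msg, ...)
  message(sprintf("[tmsmua:%s] %s", stage, sprintf(msg, ...)))

#' Run the full evoked-response analysis pipeline
#'
#' Executes the enabled stages in order -- simulate, psth, events, lmm,
#' charge, emg -- and writes population PSTH tables, the event table,
#' per-trial phase firing rates, mixed-model fits, the charge report and
#' MUAP latencies, plus a reproducibility manifest, into
#' `cfg$out_dir`. Stage dependencies are checked before execution.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- cfg$stages
  deps <- list(psth = "simulate", events = "psth", lmm = "events")
  for (s in names(deps))
    if (s %in% stages && !all(deps[[s]] %in% stages))
      stop("configuration error: stage '", s, "' requires '",
           deps[[s]], "'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)

  if ("simulate" %in% stages) {
    pipeline_log("simulate", "%d animal(s) x %d intensities x %d trials",
                 cfg$n_animals, length(cfg$intensities), cfg$n_trials)
    bts <- list()
    bts05 <- list()
    for (a in seq_len(cfg$n_animals)) {
      for (ii in seq_along(cfg$intensities)) {
        scfg <- synth_config(
          n_trials = cfg$n_trials,
          intensity_pct_mt = cfg$intensities[ii],
          orientation = cfg$orientation,
          seed = cfg$seed + 1000L * a + 100000L * ii,
          animal_id = sprintf("a%d", a))
        ses <- simulate_session(scfg, render = cfg$render)
        spikes <- if (cfg$render) {
          filt <- bandpass(ses$recording, cfg$band)
          detect_spikes(filt, detection_config(
            band = cfg$band, k = cfg$k, dead_time_ms = cfg$dead_time_ms))
        } else ses$spikes
        bts[[length(bts) + 1L]] <- bin_and_normalize(
          spikes, ses$stimlog, cfg$bin_size_ms, cfg$window_ms)
        if (cfg$short_latency)
          bts05[[length(bts05) + 1L]] <- bin_and_normalize(
            spikes, ses$stimlog, 0.5, cfg$window_ms)
      }
    }
    res$binned <- combine_binned(bts)
    if (cfg$short_latency)
      res$binned_05 <- combine_binned(bts05)
  }

  if ("psth" %in% stages) {
    avgs <- average_trials(res$binned, group_by = "intensity")
    for (av in avgs) {
      df <- data.frame(time_ms = av$centers_ms,
                       normalized_fr = av$values)
      utils::write.csv(df, file.path(cfg$out_dir, sprintf(
        "psth_%s_%g.csv", cfg$orientation, av$meta$intensity)),
        row.names = FALSE)
    }
    res$psth <- avgs
    pipeline_log("psth", "%d condition average(s) written", length(avgs))
  }

  if ("events" %in% stages) {
    top <- max(cfg$intensities)
    sel <- res$binned$trial_meta$intensity_pct_mt == top
    bt_top <- res$binned
    bt_top$matrix <- bt_top$matrix[sel, , drop = FALSE]
    bt_top$trial_meta <- bt_top$trial_meta[sel, , drop = FALSE]
    ana <- evoked_analysis(bt_top, cfg$sigma_ms, cfg$min_dur_ms,
                           cfg$max_gap_ms)
    write_events_csv(ana$events, file.path(cfg$out_dir, "events.csv"))
    res$events <- ana$events
    res$band <- ana$band
    phase_fr <- extract_phase_fr(res$binned, ana$events)
    utils::write.csv(phase_fr, file.path(cfg$out_dir, "phase_fr.csv"),
                     row.names = FALSE)
    res$phase_fr <- phase_fr
    pipeline_log("events", "%d event(s), %d labeled phase(s)",
                 nrow(ana$events),
                 sum(ana$events$label != "unclassified"))
    if (cfg$short_latency && !is.null(res$binned_05)) {
      sel05 <- res$binned_05$trial_meta$intensity_pct_mt == top
      bt05 <- res$binned_05
      bt05$matrix <- bt05$matrix[sel05, , drop = FALSE]
      bt05$trial_meta <- bt05$trial_meta[sel05, , drop = FALSE]
      sla <- short_latency_analysis(bt05)
      write_events_csv(sla$events,
                       file.path(cfg$out_dir, "short_latency_events.csv"))
      res$short_latency <- sla
      pipeline_log("events", "%d short-latency event(s)",
                   nrow(sla$events))
    }
  }

  if ("lmm" %in% stages) {
    fits <- list()
    for (ph in unique(res$phase_fr$phase)) {
      d <- res$phase_fr[res$phase_fr$phase == ph, ]
      if (length(unique(d$animal_id)) < 2L ||
          length(unique(d$intensity_pct_mt)) < 2L) next
      f <- fit_lmm(d)
      fits[[ph]] <- list(beta = f$beta, se_beta = f$se_beta,
                         intercept = f$intercept,
                         var_animal = f$var_animal,
                         var_resid = f$var_resid, F = f$F, ddf = f$ddf,
                         p = f$p, n_obs = f$n_obs, n_groups = f$n_groups,
                         method = f$method)
      pipeline_log("lmm", "%s: beta = %.3f +/- %.3f, F = %.2f, p = %.3g",
                   ph, f$beta, f$se_beta, f$F, f$p)
    }
    jsonlite::write_json(fits, file.path(cfg$out_dir, "lmm.json"),
                         auto_unbox = TRUE, digits = NA)
    res$lmm <- fits
  }

  if ("charge" %in% stages) {
    # TMS-like biphasic loop current rendered through the monitoring
    # channel and recovered back
    fs <- 1e6
    t <- seq(0, 4e-4, by = 1 / fs)
    current <- 2e-6 * sin(2 * pi * t / 4e-4)
    v <- generate_lgm_trace(current, cfg$c_in, fs)
    rep_ <- charge_per_phase(current_from_lgm(v, cfg$c_in, fs), fs,
                             c_in = cfg$c_in)
    jsonlite::write_json(
      list(q_pos_pc = rep_$q_pos_pc, q_neg_pc = rep_$q_neg_pc,
           q_total_bipolar_pc = rep_$q_total_bipolar_pc,
           peak_current_ua = rep_$peak_current_ua,
           safety_factor_low = rep_$safety_factor_low,
           safety_factor_high = rep_$safety_factor_high,
           c_in = rep_$c_in, note = rep_$note),
      file.path(cfg$out_dir, "charge.json"), auto_unbox = TRUE,
      digits = NA)
    res$charge <- rep_
    pipeline_log("charge", "bipolar charge %.3g pC",
                 rep_$q_total_bipolar_pc)
  }

  if ("emg" %in% stages) {
    rows <- list()
    for (i in seq_len(min(cfg$n_trials, 20L))) {
      e <- generate_emg(cfg$emg_latency_ms, seed = cfg$seed + 5000L + i)
      fc <- filter_emg(e$contra, e$fs)
      r <- detect_muap_onset(fc, e$fs, e$stim_onset_s)
      rows[[i]] <- data.frame(trial = i,
                              response_present = r$response_present,
                              onset_latency_ms = r$onset_latency_ms)
    }
    muap <- do.call(rbind, rows)
    utils::write.csv(muap, file.path(cfg$out_dir, "muap.csv"),
                     row.names = FALSE)
    res$muap <- muap
    pipeline_log("emg", "median onset latency %.2f ms",
                 stats::median(muap$onset_latency_ms, na.rm = TRUE))
  }

  manifest <- cfg
  manifest$spike_waveform <- NULL
  jsonlite::write_json(
    list(package = "tmsmua",
         version = as.character(utils::packageVersion("tmsmua")),
         config = unclass(manifest)),
    file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(res)
}
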