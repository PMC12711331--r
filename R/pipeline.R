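#' Build a full pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its standard
#' default: 60 Hz EMG high-pass; 40 ms rectify-integrate window (within the
#' 36-50 ms range); apnea ratio 2.5 and sigh ratio 2 over a 10-breath
#' trailing window; 8 s post-sigh window; seizure criteria >2x baseline and
#' >10 s; PGES 100 s baseline, 5 s moving window, 3 SD / >=5 s exit; PEA
#' interictal gap <5 min; 10 s sleep epochs with 0.5-4 / 4.5-8 Hz bands;
#' 6 h frequency-z-score baseline; 2 h PEA stage windows.
#'
#' @param seed integer seed used for simulation.
#' @param simulate generate input signals (`TRUE`) or read them from
#'   `input` (`FALSE`).
#' @param sim list of arguments for [sim_config()] (ignored when `stages`
#'   is given).
#' @param stages optional stage table for [generate_disease_course()].
#' @param input path to an EDF/CSV recording when `simulate = FALSE`.
#' @param movement_csv optional path to a movement-mask CSV.
#' @param day_s staging "day" length in s (default 86400; compressed
#'   simulated courses use the compressed stage length).
#' @param ... overrides for any default parameter listed below.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulate = TRUE, sim = list(),
                       stages = NULL, input = NULL, movement_csv = NULL,
                       day_s = 86400, ...) {
  cfg <- list(
    seed = as.integer(seed), simulate = simulate, sim = sim,
    stages = stages, input = input, movement_csv = movement_csv,
    day_s = day_s,
    emg_highpass_hz = 60, integrate_window_ms = 40,
    apnea_ratio = 2.5, sigh_ratio = 2, n_baseline = 10, min_baseline = 5,
    postsigh_s = 8,
    seizure_amp_ratio = 2, seizure_min_dur_s = 10, seizure_merge_gap_s = 5,
    seizure_freq_ratio = 1.5,
    pges_baseline_s = 100, pges_window_s = 5, pges_k_sd = 3,
    pea_max_gap_s = 300, pea_min_run = 3, pea_lookahead_s = 1800,
    epoch_s = 10, r_nrem = 1.5, r_rem = 1.2, a_nrem = 0.9, m_max = 3,
    zscore_baseline_h = 6, pea_window_s = 7200,
    segment_length_s = 120)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("run_config: unknown parameters: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys are [run_config()] arguments/parameters.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stages)) y$stages <- as.data.frame(y$stages)
  do.call(run_config, y)
}

pipe_stage <- function(name, expr, log) {
  log(paste0("stage ", name, " ..."))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulation (or reading), EMG conditioning, breath
#' segmentation, ECG-peak extraction, seizure/PGES/PEA detection, sleep
#' scoring, respiratory-event classification, disease staging, per-stage
#' breathing summaries with state-specific apnea/sigh rates, and terminal
#' analysis when the recording ends in death. Deterministic given the
#' config (which includes the seed). When `out_dir` is given, writes
#' `breaths.csv`, `events.csv`, `seizures.csv`, `pges.csv`, `epochs.csv`,
#' `stages.csv`, `summary.csv`, `terminal.json` and `epivent.log` there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if missing).
#' @return a list of class `epivent_report` with all tables, the signals and
#'   (for simulated input) the ground truth.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  rec <- pipe_stage("input", {
    if (isTRUE(config$simulate)) {
      if (!is.null(config$stages))
        do.call(generate_disease_course,
                c(list(seed = config$seed, stages = config$stages),
                  config$sim))
      else
        generate_recording(do.call(sim_config,
                                   c(list(seed = config$seed), config$sim)))
    } else {
      r <- read_recording(config$input)
      r$movement <- if (!is.null(config$movement_csv))
        read_movement_csv(config$movement_csv) else movement_mask()
      r$truth <- NULL
      r
    }
  }, log)

  emg_int <- pipe_stage("emg_processing", {
    hp <- emg_highpass(rec$emg, config$emg_highpass_hz)
    rectify_integrate(hp, config$integrate_window_ms)
  }, log)
  breaths <- pipe_stage("segment_breaths", segment_breaths(emg_int), log)
  log(sprintf("  %d breaths", nrow(breaths)))
  ecg_peaks <- pipe_stage("detect_ecg_peaks", detect_ecg_peaks(rec$emg), log)

  seizures <- pipe_stage("detect_seizures", detect_seizures(
    rec$eeg, amp_ratio = config$seizure_amp_ratio,
    min_dur_s = config$seizure_min_dur_s,
    merge_gap_s = config$seizure_merge_gap_s,
    freq_ratio = config$seizure_freq_ratio), log)
  log(sprintf("  %d seizures", nrow(seizures)))

  pges <- pipe_stage("measure_pges", {
    rows <- list()
    prior <- NULL
    pwr <- if (nrow(seizures)) zp_bandpass(
      rec$eeg$samples, rec$eeg$rate, 0.5,
      min(50, 0.45 * rec$eeg$rate), 2)^2 else NULL
    for (k in seq_len(nrow(seizures))) {
      if (seizures$start[k] - rec$eeg$start < config$pges_baseline_s) next
      r <- tryCatch(measure_pges(
        rec$eeg, seizures[k, ], prior_events = prior,
        baseline_s = config$pges_baseline_s,
        window_s = config$pges_window_s, k_sd = config$pges_k_sd,
        power = pwr), error = function(e) NULL)
      if (is.null(r)) next
      rows <- c(rows, list(data.frame(start = r$seizure_end,
                                      duration = r$duration,
                                      censored = r$censored)))
      prior <- rbind(prior, data.frame(
        start = seizures$start[k],
        end = r$seizure_end + r$duration))
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(start = numeric(0), duration = numeric(0),
                 censored = logical(0))
  }, log)

  pea_onset <- pipe_stage("detect_pea_onset", detect_pea_onset(
    seizures, ts_end(rec$eeg), max_gap_s = config$pea_max_gap_s,
    min_run = config$pea_min_run, lookahead_s = config$pea_lookahead_s), log)

  epochs <- pipe_stage("score_epochs", score_epochs(
    rec$eeg, emg_int, rec$movement, seizures, pges, pea_onset,
    epoch_s = config$epoch_s, r_nrem = config$r_nrem, r_rem = config$r_rem,
    a_nrem = config$a_nrem, m_max = config$m_max), log)

  sighs <- pipe_stage("detect_sighs", detect_sighs(
    breaths, epochs, ratio = config$sigh_ratio,
    n_baseline = config$n_baseline, min_baseline = config$min_baseline), log)
  apneas <- pipe_stage("detect_apneas", detect_apneas(
    breaths, epochs, sighs, ratio = config$apnea_ratio,
    n_baseline = config$n_baseline, min_baseline = config$min_baseline,
    postsigh_s = config$postsigh_s), log)
  log(sprintf("  %d sighs, %d apneas (%d post-sigh)", nrow(sighs),
              nrow(apneas), sum(apneas$kind == "postsigh_apnea")))

  ## death = end of breathing, when the recording ends breathless
  death_time <- NULL
  if (nrow(breaths) &&
      ts_end(rec$emg) - max(breaths$onset) >= 60)
    death_time <- max(breaths$offset)

  stages <- pipe_stage("stage_recording", stage_recording(
    seizures, pea_onset, death_time, day_s = config$day_s,
    pea_window_s = config$pea_window_s), log)

  summary_df <- pipe_stage("summaries", {
    baseline_sigh_amp <- baseline_sigh_amplitude(breaths, sighs, seizures)
    resp <- rbind(sighs, apneas)
    rows <- lapply(seq_len(nrow(stages)), function(j) {
      win <- c(stages$start[j], stages$end[j])
      seg <- if (win[2L] - win[1L] >= config$segment_length_s)
        select_stable_segment(breaths, win, config$segment_length_s,
                              rec$movement, resp) else NULL
      s <- if (is.null(seg)) {
        data.frame(seg_start = NA_real_, seg_end = NA_real_,
                   n_breaths = 0L, mean_freq = NA_real_, cv_freq = NA_real_,
                   norm_amp = NA_real_, mean_insp_dur = NA_real_,
                   mean_area_norm = NA_real_, insufficient = TRUE)
      } else segment_summary(breaths, seg, baseline_sigh_amp,
                             allow_any_length = TRUE)
      cbind(data.frame(stage = stages$label[j], stage_start = stages$start[j],
                       stage_end = stages$end[j]),
            s, state_event_rates(epochs, apneas, sighs, win))
    })
    do.call(rbind, rows)
  }, log)

  terminal <- NULL
  if (!is.null(death_time))
    terminal <- pipe_stage("terminal_analysis", analyze_terminal(
      breaths, ecg_peaks, rec$eeg, apneas), log)

  report <- structure(list(
    config = config, breaths = breaths, ecg_peaks = ecg_peaks,
    seizures = seizures, pges = pges, pea_onset = pea_onset,
    epochs = epochs, sighs = sighs, apneas = apneas, stages = stages,
    summary = summary_df, terminal = terminal, death_time = death_time,
    eeg = rec$eeg, emg = rec$emg, movement = rec$movement,
    truth = rec$truth, log = log_lines), class = "epivent_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(breaths, file.path(out_dir, "breaths.csv"),
                     row.names = FALSE)
    write_events_csv(event_table(rbind(sighs, apneas), seizures, pges),
                     file.path(out_dir, "events.csv"))
    utils::write.csv(seizures, file.path(out_dir, "seizures.csv"),
                     row.names = FALSE)
    utils::write.csv(pges, file.path(out_dir, "pges.csv"),
                     row.names = FALSE)
    utils::write.csv(epochs, file.path(out_dir, "epochs.csv"),
                     row.names = FALSE)
    utils::write.csv(stages, file.path(out_dir, "stages.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(terminal))
      jsonlite::write_json(unclass(terminal),
                           file.path(out_dir, "terminal.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, file.path(out_dir, "epivent.log"))
  }
  report
}

## mean sigh peak before the first seizure (preseizure baseline); falls back
## to twice the mean breath peak (flagged via attribute) when no baseline
## sigh was detected
baseline_sigh_amplitude <- function(breaths, sighs, seizures) {
  t0 <- if (nrow(seizures)) min(seizures$start) else Inf
  s <- sighs[sighs$time < t0, , drop = FALSE]
  if (nrow(s)) {
    pk <- breaths$peak[match(s$time, breaths$onset)]
    return(mean(pk, na.rm = TRUE))
  }
  out <- 2 * mean(breaths$peak)
  attr(out, "fallback") <- TRUE
  out
}

## apnea/sigh rates per hour of scored NREM and REM_IW time inside a window
state_event_rates <- function(epochs, apneas, sighs, win) {
  ep <- epochs[epochs$start >= win[1L] & epochs$end <= win[2L], ,
               drop = FALSE]
  out <- data.frame(row.names = 1L)
  spont <- apneas[apneas$kind == "apnea", , drop = FALSE]
  for (st in c("NREM", "REM_IW")) {
    hours <- sum(ep$state == st) * (if (nrow(ep)) ep$end[1L] - ep$start[1L]
                                    else 10) / 3600
    a <- sum(spont$state == st & spont$time >= win[1L] &
               spont$time < win[2L])
    s <- sum(sighs$state == st & sighs$time >= win[1L] &
               sighs$time < win[2L])
    out[[paste0("hours_", st)]] <- hours
    out[[paste0("apnea_per_h_", st)]] <- if (hours > 0) a / hours else NA_real_
    out[[paste0("sigh_per_h_", st)]] <- if (hours > 0) s / hours else NA_real_
  }
  out
}

#' @export
print.epivent_report <- function(x, ...) {
  cat("<epivent_report>\n")
  cat(sprintf("  recording: %.0f s EEG @ %g Hz, EMG @ %g Hz\n",
              ts_duration(x$eeg), x$eeg$rate, x$emg$rate))
  cat(sprintf("  breaths: %d   sighs: %d   apneas: %d (%d post-sigh)\n",
              nrow(x$breaths), nrow(x$sighs), nrow(x$apneas),
              sum(x$apneas$kind == "postsigh_apnea")))
  cat(sprintf("  seizures: %d   PGES: %d   PEA onset: %s\n",
              nrow(x$seizures), nrow(x$pges),
              if (is.null(x$pea_onset)) "none" else
                sprintf("%.0f s", x$pea_onset)))
  cat(sprintf("  stages: %s\n", paste(x$stages$label, collapse = ", ")))
  if (!is.null(x$terminal))
    cat(sprintf("  terminal: last breath %.1f s, last ECG %s, pattern %s\n",
                x$terminal$last_breath,
                if (is.na(x$terminal$last_ecg)) "none" else
                  sprintf("%.1f s", x$terminal$last_ecg),
                x$terminal$pattern))
  invisible(x)
}
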