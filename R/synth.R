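#' Configuration for the synthetic telemetry generator
#'
#' Describes one simulated dual-channel recording: baseline eupnea at
#' `breath_rate` breaths/s realised as inspiratory EMG bursts, a contaminating
#' periodic ECG spike train, state-dependent EEG background (slow high-amplitude
#' activity in NREM, faster moderate activity in REM/inactive wake), plus a
#' fully programmed schedule of sighs, apneas, seizures, postictal suppression,
#' PEA, progressive slowing/deepening of breathing and terminal events. The
#' schedule is returned alongside the signals as ground truth, which is what
#' makes the generator usable as a detector oracle.
#'
#' @param duration recording length in s.
#' @param seed integer RNG seed; the output is a pure function of the config
#'   (which includes the seed).
#' @param breath_rate baseline breathing frequency in breaths/s (default 4,
#'   typical for a resting adult mouse).
#' @param breath_burst_ms inspiratory burst duration in ms (default 80).
#' @param breath_amp burst amplitude in arbitrary units.
#' @param breath_jitter fractional SD of the inter-breath interval (default
#'   0.02; breathing is quasi-periodic, not clockwork).
#' @param sigh_amp_ratio amplitude factor applied to scheduled sighs
#'   (default 2.5; comfortably above the 2x detection threshold).
#' @param ecg_rate heart rate in beats/s (default 10).
#' @param ecg_amp_ratio ECG spike peak relative to `breath_amp` (default 0.3);
#'   0 disables the cardiac train.
#' @param noise_sd SD of the broadband EMG noise floor.
#' @param emg_rate,eeg_rate sampling rates in Hz (defaults 1000 / 500).
#' @param eeg_floor_sd SD of the broadband EEG noise floor.
#' @param nrem_amp,rem_amp RMS of the band-limited EEG background per state
#'   (defaults 3 / 1.8).
#' @param nrem_s,rem_s lengths of the alternating NREM / REM-inactive blocks
#'   in s (defaults 240 / 120).
#' @param pges_amp amplitude factor applied to EEG during programmed
#'   postictal suppression (default 0.2).
#' @param sigh_times numeric vector: the first breath at/after each time
#'   becomes a sigh.
#' @param apnea_schedule data frame with columns `time`, `period_ratio`
#'   (> 1): the first inter-breath gap starting at/after `time` is stretched
#'   by `period_ratio`.
#' @param seizure_schedule data frame with columns `start`, `duration`,
#'   `amp_ratio` (> 1), `freq` (Hz): EEG segments replaced by
#'   sinusoid-dominated activity at `amp_ratio` times the background RMS of
#'   the whole recording (computed before any seizure is inserted).
#' @param pges_durations numeric vector, one suppression duration in s per
#'   scheduled seizure (0 = none).
#' @param pea_onset optional time in s after which sleep scoring is undefined
#'   (recorded in ground truth; usually set by [generate_disease_course()]).
#' @param slowing_profile optional data frame `time`, `freq_scale`,
#'   `amp_scale`, `dur_scale`: piecewise-linear trajectory of breathing
#'   frequency, burst amplitude and burst duration (progressive slowing and
#'   deepening).
#' @param movement optional [movement_mask()] of active-wake intervals.
#' @param terminal optional list `(apnea_time, asystole_time, tonic)`:
#'   the last inspiratory burst is placed at `apnea_time` (a prolonged tonic
#'   burst if `tonic`), and the ECG train stops at `asystole_time`
#'   (> `apnea_time`).
#' @return an object of class `sim_config`.
#' @seealso [generate_recording()], [generate_disease_course()]
#' @export
sim_config <- function(duration, seed = 1L,
                       breath_rate = 4, breath_burst_ms = 80, breath_amp = 1,
                       breath_jitter = 0.02, sigh_amp_ratio = 2.5,
                       ecg_rate = 10, ecg_amp_ratio = 0.3, noise_sd = 0.05,
                       emg_rate = 1000, eeg_rate = 500, eeg_floor_sd = 0.3,
                       nrem_amp = 3, rem_amp = 1.8, nrem_s = 240, rem_s = 120,
                       pges_amp = 0.2,
                       sigh_times = numeric(),
                       apnea_schedule = NULL,
                       seizure_schedule = NULL,
                       pges_durations = NULL,
                       pea_onset = NULL,
                       slowing_profile = NULL,
                       movement = NULL,
                       terminal = NULL) {
  if (duration <= 0) stop("sim_config: duration must be positive")
  if (!is.null(apnea_schedule)) {
    apnea_schedule <- as.data.frame(apnea_schedule)
    stopifnot(all(c("time", "period_ratio") %in% names(apnea_schedule)))
    if (any(apnea_schedule$period_ratio <= 1))
      stop("sim_config: apnea period_ratio must be > 1")
    if (any(apnea_schedule$time >= duration))
      stop("sim_config: apnea schedule exceeds recording duration")
    apnea_schedule <- apnea_schedule[order(apnea_schedule$time), , drop = FALSE]
  }
  if (!is.null(seizure_schedule)) {
    seizure_schedule <- as.data.frame(seizure_schedule)
    stopifnot(all(c("start", "duration", "amp_ratio", "freq") %in%
                    names(seizure_schedule)))
    if (any(seizure_schedule$amp_ratio <= 1))
      stop("sim_config: seizure amp_ratio must be > 1")
    if (any(seizure_schedule$start + seizure_schedule$duration > duration))
      stop("sim_config: seizure schedule exceeds recording duration")
    seizure_schedule <-
      seizure_schedule[order(seizure_schedule$start), , drop = FALSE]
  }
  if (any(sigh_times >= duration))
    stop("sim_config: sigh schedule exceeds recording duration")
  if (!is.null(pges_durations)) {
    ns <- if (is.null(seizure_schedule)) 0L else nrow(seizure_schedule)
    if (length(pges_durations) != ns)
      stop("sim_config: pges_durations must have one entry per seizure")
  }
  if (!is.null(terminal)) {
    stopifnot(is.list(terminal), !is.null(terminal$apnea_time),
              !is.null(terminal$asystole_time))
    terminal$tonic <- isTRUE(terminal$tonic)
    if (terminal$asystole_time <= terminal$apnea_time)
      stop("sim_config: terminal asystole_time must be after apnea_time")
    if (terminal$asystole_time >= duration)
      stop("sim_config: terminal schedule exceeds recording duration")
  }
  if (!is.null(slowing_profile)) {
    slowing_profile <- as.data.frame(slowing_profile)
    stopifnot("time" %in% names(slowing_profile))
    for (col in c("freq_scale", "amp_scale", "dur_scale"))
      if (is.null(slowing_profile[[col]])) slowing_profile[[col]] <- 1
  }
  structure(list(
    duration = duration, seed = as.integer(seed),
    breath_rate = breath_rate, breath_burst_ms = breath_burst_ms,
    breath_amp = breath_amp, breath_jitter = breath_jitter,
    sigh_amp_ratio = sigh_amp_ratio,
    ecg_rate = ecg_rate, ecg_amp_ratio = ecg_amp_ratio, noise_sd = noise_sd,
    emg_rate = emg_rate, eeg_rate = eeg_rate, eeg_floor_sd = eeg_floor_sd,
    nrem_amp = nrem_amp, rem_amp = rem_amp, nrem_s = nrem_s, rem_s = rem_s,
    pges_amp = pges_amp,
    sigh_times = sort(as.numeric(sigh_times)),
    apnea_schedule = apnea_schedule,
    seizure_schedule = seizure_schedule,
    pges_durations = pges_durations,
    pea_onset = pea_onset,
    slowing_profile = slowing_profile,
    movement = movement,
    terminal = terminal), class = "sim_config")
}

profile_fun <- function(profile, col) {
  if (is.null(profile) || nrow(profile) < 2L) {
    v <- if (is.null(profile)) 1 else profile[[col]][1L]
    function(t) rep(v, length(t))
  } else {
    stats::approxfun(profile$time, profile[[col]], rule = 2)
  }
}

## Draw the breath onset schedule (the only RNG consumer besides the signal
## noise). Returns breaths, realised apneas, and sigh bookkeeping.
schedule_breaths <- function(cfg) {
  end_t <- if (!is.null(cfg$terminal)) cfg$terminal$apnea_time else cfg$duration
  pf <- profile_fun(cfg$slowing_profile, "freq_scale")
  pa <- profile_fun(cfg$slowing_profile, "amp_scale")
  pd <- profile_fun(cfg$slowing_profile, "dur_scale")
  sigh_q <- cfg$sigh_times
  ap <- cfg$apnea_schedule
  ai <- 1L
  n_guess <- as.integer(cfg$duration * cfg$breath_rate * 1.2) + 16L
  onset <- amp <- bdur <- numeric(n_guess)
  is_sigh <- logical(n_guess)
  ap_start <- ap_dur <- ap_ratio <- numeric(0)
  t <- 0.25 / cfg$breath_rate
  i <- 0L
  while (t < end_t - 0.05) {
    i <- i + 1L
    a <- cfg$breath_amp * pa(t)
    d <- cfg$breath_burst_ms / 1000 * pd(t)
    sg <- FALSE
    if (length(sigh_q) && t >= sigh_q[1L]) {
      a <- a * cfg$sigh_amp_ratio
      d <- d * 1.15
      sg <- TRUE
      sigh_q <- sigh_q[-1L]
    }
    onset[i] <- t; amp[i] <- a; bdur[i] <- d; is_sigh[i] <- sg
    period <- 1 / (cfg$breath_rate * pf(t)) *
      max(0.4, 1 + cfg$breath_jitter * stats::rnorm(1))
    if (!is.null(ap) && ai <= nrow(ap) && t >= ap$time[ai]) {
      ratio <- ap$period_ratio[ai]
      period <- period * ratio
      ap_start <- c(ap_start, t + d)
      ap_dur <- c(ap_dur, period)
      ap_ratio <- c(ap_ratio, ratio)
      ai <- ai + 1L
    }
    t <- t + period
  }
  if (!is.null(cfg$terminal)) {
    ## final inspiratory burst exactly at the programmed terminal-apnea time
    i <- i + 1L
    onset[i] <- cfg$terminal$apnea_time
    amp[i] <- cfg$breath_amp * pa(end_t) * (if (cfg$terminal$tonic) 1.5 else 1)
    bdur[i] <- if (cfg$terminal$tonic) 6 * cfg$breath_burst_ms / 1000 *
      pd(end_t) else cfg$breath_burst_ms / 1000 * pd(end_t)
    is_sigh[i] <- FALSE
  }
  keep <- seq_len(i)
  breaths <- data.frame(onset = onset[keep], amp = amp[keep],
                        burst_dur = bdur[keep], is_sigh = is_sigh[keep])
  sighs <- breaths[breaths$is_sigh, , drop = FALSE]
  postsigh <- rep(FALSE, length(ap_start))
  if (nrow(sighs) && length(ap_start)) {
    sigh_off <- sighs$onset + sighs$burst_dur
    for (k in seq_along(ap_start))
      postsigh[k] <- any(ap_start[k] - sigh_off >= 0 &
                           ap_start[k] - sigh_off <= 8)
  }
  list(breaths = breaths,
       apneas = data.frame(time = ap_start, duration = ap_dur,
                           ratio = ap_ratio, postsigh = postsigh),
       sighs = data.frame(time = sighs$onset,
                          offset = sighs$onset + sighs$burst_dur))
}

state_blocks <- function(cfg) {
  starts <- ends <- numeric(0); states <- character(0)
  t <- 0; nrem <- TRUE
  while (t < cfg$duration) {
    len <- if (nrem) cfg$nrem_s else cfg$rem_s
    starts <- c(starts, t); ends <- c(ends, min(t + len, cfg$duration))
    states <- c(states, if (nrem) "NREM" else "REM_IW")
    t <- t + len; nrem <- !nrem
  }
  data.frame(start = starts, end = ends, state = states,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic EEG/EMG recording with programmed ground truth
#'
#' Renders the event schedule in a [sim_config()] into raw signals. The EMG
#' channel is a broadband noise floor plus noise-modulated raised-cosine
#' inspiratory bursts and a biphasic ECG spike train (8 ms wide, narrow
#' relative to the rectify-integrate window so that integration suppresses
#' it). The EEG channel is state-dependent band-limited noise
#' (0.5-4 Hz at high amplitude in NREM, 4.5-8 Hz at moderate amplitude in
#' REM/inactive wake) over a broadband floor; scheduled seizures replace the
#' background with a tapered sinusoid-plus-harmonic at the programmed
#' multiple of the local baseline RMS, each optionally followed by an
#' amplitude-suppressed postictal segment with a sharp (0.5 s) recovery.
#' Identical config (including its seed) gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @return a list with elements `eeg`, `emg` ([time_series()]),
#'   `movement` ([movement_mask()]) and `truth` (class `ground_truth`: the
#'   programmed breaths, sighs, apneas, seizures, PGES intervals, ECG beat
#'   times, sleep-epoch states, PEA onset and terminal schedule).
#' @examples
#' rec <- generate_recording(sim_config(duration = 30, seed = 42))
#' nrow(rec$truth$breaths)
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("generate_recording: config must be a sim_config")
  cfg <- config
  set.seed(cfg$seed)
  sch <- schedule_breaths(cfg)

  ## ---- EMG ----
  n_emg <- round(cfg$duration * cfg$emg_rate)
  emg <- stats::rnorm(n_emg, 0, cfg$noise_sd)
  br <- sch$breaths
  for (k in seq_len(nrow(br))) {
    i0 <- floor(br$onset[k] * cfg$emg_rate) + 1L
    len <- max(8L, round(br$burst_dur[k] * cfg$emg_rate))
    idx <- i0:min(i0 + len - 1L, n_emg)
    u <- seq(0, 1, length.out = length(idx))
    env <- 0.5 * (1 - cos(2 * pi * u))
    emg[idx] <- emg[idx] + br$amp[k] * env * stats::rnorm(length(idx))
  }
  ecg_beats <- numeric(0)
  if (cfg$ecg_amp_ratio > 0) {
    stop_t <- if (!is.null(cfg$terminal)) cfg$terminal$asystole_time else
      cfg$duration
    ecg_beats <- seq(0.05, stop_t - 0.02, by = 1 / cfg$ecg_rate)
    tw <- max(4L, round(0.008 * cfg$emg_rate))
    tmpl <- sin(2 * pi * seq_len(tw) / tw) * cfg$ecg_amp_ratio * cfg$breath_amp
    bi <- floor(ecg_beats * cfg$emg_rate) + 1L
    ok <- bi + tw - 1L <= n_emg
    idx <- as.vector(outer(bi[ok], 0:(tw - 1L), "+"))
    emg[idx] <- emg[idx] + rep(tmpl, each = sum(ok))
  }

  ## ---- EEG background ----
  n_eeg <- round(cfg$duration * cfg$eeg_rate)
  eeg <- stats::rnorm(n_eeg, 0, cfg$eeg_floor_sd)
  blocks <- state_blocks(cfg)
  for (k in seq_len(nrow(blocks))) {
    i0 <- floor(blocks$start[k] * cfg$eeg_rate) + 1L
    i1 <- min(round(blocks$end[k] * cfg$eeg_rate), n_eeg)
    len <- i1 - i0 + 1L
    if (len < 50L) next
    band <- if (blocks$state[k] == "NREM") c(0.5, 4) else c(4.5, 8)
    a <- if (blocks$state[k] == "NREM") cfg$nrem_amp else cfg$rem_amp
    y <- zp_bandpass(stats::rnorm(len), cfg$eeg_rate, band[1], band[2],
                     order = 2)
    eeg[i0:i1] <- eeg[i0:i1] + y / stats::sd(y) * a
  }
  background <- eeg
  bg_rms <- rms(background)

  ## ---- seizures + postictal suppression ----
  sz <- cfg$seizure_schedule
  pg_start <- pg_dur <- numeric(0)
  if (!is.null(sz) && nrow(sz)) {
    for (k in seq_len(nrow(sz))) {
      i0 <- floor(sz$start[k] * cfg$eeg_rate) + 1L
      i1 <- min(round((sz$start[k] + sz$duration[k]) * cfg$eeg_rate), n_eeg)
      len <- i1 - i0 + 1L
      base_rms <- bg_rms
      tt <- (seq_len(len) - 1) / cfg$eeg_rate
      wave <- sin(2 * pi * sz$freq[k] * tt) +
        0.3 * sin(4 * pi * sz$freq[k] * tt) + 0.1 * stats::rnorm(len)
      wave <- wave / rms(wave) * sz$amp_ratio[k] * base_rms
      taper_n <- min(round(0.25 * cfg$eeg_rate), len %/% 4L)
      if (taper_n > 1L) {
        ramp <- 0.5 * (1 - cos(pi * seq_len(taper_n) / taper_n))
        wave[seq_len(taper_n)] <- wave[seq_len(taper_n)] * ramp
        wave[(len - taper_n + 1L):len] <- wave[(len - taper_n + 1L):len] *
          rev(ramp)
      }
      eeg[i0:i1] <- wave
      d <- if (is.null(cfg$pges_durations)) 0 else cfg$pges_durations[k]
      if (d > 0) {
        s_end <- sz$start[k] + sz$duration[k]
        p0 <- i1 + 1L
        p1 <- min(round((s_end + d) * cfg$eeg_rate), n_eeg)
        if (k < nrow(sz)) p1 <- min(p1, floor(sz$start[k + 1L] * cfg$eeg_rate))
        if (p1 >= p0) {
          eeg[p0:p1] <- eeg[p0:p1] * cfg$pges_amp
          r0 <- p1 + 1L
          r1 <- min(r0 + round(0.5 * cfg$eeg_rate), n_eeg)
          if (r1 >= r0) {
            u <- seq(0, 1, length.out = r1 - r0 + 1L)
            fac <- cfg$pges_amp + (1 - cfg$pges_amp) * 0.5 * (1 - cos(pi * u))
            eeg[r0:r1] <- eeg[r0:r1] * fac
          }
          pg_start <- c(pg_start, s_end)
          pg_dur <- c(pg_dur, (p1 - round(s_end * cfg$eeg_rate)) /
                        cfg$eeg_rate)
        }
      }
    }
  }

  ## terminal EEG collapse: power decays after the last breath, as cortical
  ## activity fails with circulatory arrest
  eeg_decay_start <- NULL
  if (!is.null(cfg$terminal)) {
    eeg_decay_start <- cfg$terminal$apnea_time + 5
    d0 <- floor(eeg_decay_start * cfg$eeg_rate) + 1L
    if (d0 < n_eeg) {
      dn <- min(d0 + 20L * cfg$eeg_rate, n_eeg)
      u <- seq(0, 1, length.out = dn - d0 + 1L)
      eeg[d0:dn] <- eeg[d0:dn] * (1 - 0.95 * u)
      if (dn < n_eeg) eeg[(dn + 1L):n_eeg] <- eeg[(dn + 1L):n_eeg] * 0.05
    }
  }

  movement <- cfg$movement %||% movement_mask()
  seizures <- if (is.null(sz) || !nrow(sz)) {
    data.frame(start = numeric(0), end = numeric(0))
  } else {
    data.frame(start = sz$start, end = sz$start + sz$duration,
               amp_ratio = sz$amp_ratio, freq = sz$freq)
  }
  pges <- data.frame(start = pg_start, duration = pg_dur)
  truth_epochs <- truth_epoch_states(cfg, blocks, movement, seizures, pges)

  truth <- structure(list(
    breaths = sch$breaths,
    sighs = sch$sighs,
    apneas = sch$apneas,
    seizures = seizures,
    pges = pges,
    ecg_beats = ecg_beats,
    epochs = truth_epochs,
    pea_onset = cfg$pea_onset,
    terminal = if (is.null(cfg$terminal)) NULL else
      list(last_breath = cfg$terminal$apnea_time,
           asystole_time = cfg$terminal$asystole_time,
           tonic = cfg$terminal$tonic,
           eeg_decay_start = eeg_decay_start),
    blocks = blocks,
    duration = cfg$duration), class = "ground_truth")

  list(eeg = time_series(eeg, cfg$eeg_rate, 0, "EEG"),
       emg = time_series(emg, cfg$emg_rate, 0, "DiaEMG"),
       movement = movement,
       truth = truth)
}

## Programmed 10 s epoch states, same priority order as score_epochs():
## post-PEA OTH > SEIZ > PGES > MVM > scheduled background state.
truth_epoch_states <- function(cfg, blocks, movement, seizures, pges,
                               epoch_s = 10) {
  starts <- seq(0, cfg$duration - epoch_s, by = epoch_s)
  ends <- starts + epoch_s
  st <- blocks$state[findInterval(starts, blocks$start)]
  st[overlaps_intervals(starts, ends, movement)] <- "MVM"
  if (nrow(pges))
    st[overlaps_intervals(starts, ends,
                          intervals(pges$start, pges$start + pges$duration))] <-
      "PGES"
  if (nrow(seizures))
    st[overlaps_intervals(starts, ends,
                          intervals(seizures$start, seizures$end))] <- "SEIZ"
  if (!is.null(cfg$pea_onset)) st[starts >= cfg$pea_onset] <- "OTH"
  data.frame(start = starts, end = ends, state = st, stringsAsFactors = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %.0f s: %d breaths, %d sighs, ",
                     "%d apneas, %d seizures, %d PGES\n"),
              x$duration, nrow(x$breaths), nrow(x$sighs), nrow(x$apneas),
              nrow(x$seizures), nrow(x$pges)))
  if (!is.null(x$pea_onset)) cat(sprintf("  PEA onset at %.0f s\n", x$pea_onset))
  if (!is.null(x$terminal))
    cat(sprintf("  terminal apnea %.1f s, asystole %.1f s\n",
                x$terminal$last_breath, x$terminal$asystole_time))
  invisible(x)
}

#' Simulate a compressed disease course with escalating seizures
#'
#' Builds a multi-stage recording in which the seizure rate escalates from
#' stage to stage (each stage is one compressed "day": its seizure count is
#' a Poisson draw at the requested daily rate), breathing progressively slows and deepens over
#' the second half of the course, apnea incidence rises with seizure burden,
#' and the course ends in persistent epileptiform activity (seizures every
#' few minutes), a terminal apnea and, after a programmed lag, asystole.
#'
#' @param seed integer RNG seed.
#' @param stages data frame (or matrix) with columns `seizures_per_day` and
#'   `hours`: the requested daily seizure rate and the compressed length of
#'   each stage.
#' @param pea_hours length of the terminal PEA phase in hours (default 0.3).
#' @param terminal_lag seconds from terminal apnea to asystole (default 30).
#' @param terminal_tonic should the final inspiratory burst be a prolonged
#'   tonic burst?
#' @param enforce_monotone force per-stage seizure counts to be nondecreasing
#'   wherever the requested rates are (default `TRUE`), preserving the
#'   escalating-course contract against Poisson sampling noise.
#' @param ... further arguments passed to [sim_config()] (e.g. `noise_sd`).
#' @return as [generate_recording()], with `truth$stages` (per-stage windows,
#'   requested rates and realised seizure counts) attached.
#' @export
generate_disease_course <- function(seed, stages, pea_hours = 0.3,
                                    terminal_lag = 30, terminal_tonic = FALSE,
                                    enforce_monotone = TRUE, ...) {
  stages <- as.data.frame(stages)
  stopifnot(all(c("seizures_per_day", "hours") %in% names(stages)),
            nrow(stages) >= 1L)
  if (any(stages$hours <= 0))
    stop("generate_disease_course: zero-length stage")
  set.seed(as.integer(seed))
  stage_end <- cumsum(stages$hours) * 3600
  stage_start <- c(0, stage_end[-length(stage_end)])
  course_end <- stage_end[length(stage_end)]
  pea_len <- pea_hours * 3600
  duration <- course_end + pea_len + 180

  ## per-stage seizure schedules; each stage is one compressed "day", so
  ## the Poisson mean is the requested daily rate itself
  sz_start <- sz_dur <- numeric(0)
  counts <- integer(nrow(stages))
  prev <- 0L
  for (j in seq_len(nrow(stages))) {
    n <- stats::rpois(1L, stages$seizures_per_day[j])
    if (enforce_monotone && j > 1L &&
        stages$seizures_per_day[j] >= stages$seizures_per_day[j - 1L])
      n <- max(n, prev)
    ## keep interictal gaps clear of the PEA criterion (>= 400 s separation)
    room <- floor((stages$hours[j] * 3600 - 150) / 400)
    n <- min(n, max(room, 0L))
    if (n > 0L) {
      slots <- sort(stats::runif(n, stage_start[j] + 60,
                                 stage_end[j] - 90))
      ## enforce >= 400 s separation deterministically
      for (k in seq_along(slots)[-1L])
        if (slots[k] - slots[k - 1L] < 400) slots[k] <- slots[k - 1L] + 400
      slots <- slots[slots < stage_end[j] - 90]
      d <- stats::runif(length(slots), 20, 40)
      sz_start <- c(sz_start, slots); sz_dur <- c(sz_dur, d)
      n <- length(slots)
    }
    counts[j] <- n
    prev <- n
  }
  counts_realised <- counts

  ## PEA phase: seizures every 2-4 min until the terminal window. The
  ## onset sits a clear 350 s after the last staged stage so the transition
  ## to sub-5-min gaps happens at the labelled onset, not one event early.
  pea_onset <- course_end + 350
  t <- pea_onset
  pea_start <- numeric(0)
  while (t < course_end + pea_len - 120) {
    pea_start <- c(pea_start, t)
    t <- t + 30 + stats::runif(1, 90, 210)
  }
  sz_start <- c(sz_start, pea_start)
  sz_dur <- c(sz_dur, rep(30, length(pea_start)))
  ord <- order(sz_start)
  sz <- data.frame(start = sz_start[ord], duration = sz_dur[ord],
                   amp_ratio = stats::runif(length(sz_start), 3, 4),
                   freq = 8)
  pges_durations <- stats::runif(nrow(sz), 15, 30)
  pges_durations[sz$start >= pea_onset] <- 8   # minimal recovery between PEA events

  ## sighs every ~5 min; apnea incidence rises with seizure burden
  sigh_times <- seq(150, duration - 200, by = 300) +
    stats::runif(length(seq(150, duration - 200, by = 300)), -60, 60)
  ap_time <- numeric(0)
  for (j in seq_len(nrow(stages))) {
    per_h <- 0.5 + 0.4 * stages$seizures_per_day[j]
    n <- stats::rpois(1L, per_h * stages$hours[j])
    if (n > 0L)
      ap_time <- c(ap_time, sort(stats::runif(n, stage_start[j] + 30,
                                              stage_end[j] - 30)))
  }
  apnea_schedule <- if (length(ap_time))
    data.frame(time = ap_time,
               period_ratio = stats::runif(length(ap_time), 2.8, 3.6)) else NULL

  ## slowing/deepening over the second half of the course, steepening in
  ## the final minutes before death
  prof <- data.frame(
    time = c(0, 0.5 * course_end, course_end, duration - 600, duration),
    freq_scale = c(1, 1, 0.55, 0.5, 0.28),
    amp_scale = c(1, 1, 1.8, 2, 2.2),
    dur_scale = c(1, 1, 2, 2.2, 2.5))

  cfg <- sim_config(duration = duration, seed = as.integer(seed),
                    sigh_times = sigh_times[sigh_times < duration - 200],
                    apnea_schedule = apnea_schedule,
                    seizure_schedule = sz,
                    pges_durations = pges_durations,
                    pea_onset = pea_onset,
                    slowing_profile = prof,
                    terminal = list(apnea_time = duration - 120,
                                    asystole_time = duration - 120 +
                                      terminal_lag,
                                    tonic = terminal_tonic),
                    ...)
  out <- generate_recording(cfg)
  out$truth$stages <- data.frame(
    start = stage_start, end = stage_end,
    seizures_per_day = stages$seizures_per_day,
    n_seizures = counts_realised)
  out$config <- cfg
  out
}
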