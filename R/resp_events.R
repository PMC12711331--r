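## Apnea / sigh / post-sigh classification and normalized breathing metrics.
##
## All trailing baselines are computed "within the same behavioral state":
## only preceding breaths whose epoch state matches the current breath's are
## eligible, sighs are excluded from subsequent baselines (so one sigh cannot
## mask the next, and a sigh's long period cannot inflate the apnea
## baseline), at least `min_baseline` of the nominal 10 breaths are required,
## and the scan never reaches back more than `lookback_s` seconds.

breath_state_vec <- function(breaths, epochs) {
  if (is.null(epochs) || nrow(breaths) == 0L)
    return(rep("ALL", nrow(breaths)))
  vapply(breaths$onset, function(t) {
    if (t < epochs$start[1L] || t >= epochs$start[nrow(epochs)] + 10)
      return("OTH")
    state_at(epochs, t)
  }, character(1))
}

resp_event_frame <- function(kind = character(), time = numeric(),
                             duration = numeric(), ratio = numeric(),
                             state = character()) {
  data.frame(kind = kind, time = time, duration = duration, ratio = ratio,
             state = state, stringsAsFactors = FALSE)
}

## mean of up to n_baseline trailing eligible values; NA when fewer than
## min_baseline are available within lookback_s
trailing_baseline <- function(i, onset, value, eligible, state,
                              n_baseline, min_baseline, lookback_s) {
  vals <- numeric(0)
  j <- i - 1L
  while (j >= 1L && length(vals) < n_baseline) {
    if (onset[i] - onset[j] > lookback_s) break
    if (eligible[j] && state[j] == state[i] && is.finite(value[j]))
      vals <- c(vals, value[j])
    j <- j - 1L
  }
  if (length(vals) >= min_baseline) mean(vals) else NA_real_
}

#' Detect sighs in a breath sequence
#'
#' A breath is a sigh when its peak amplitude is at least `ratio` (default 2,
#' inclusive) times the mean peak of the preceding 10 breaths in the same
#' sleep/wake state. Previously flagged sighs are excluded from the trailing
#' baseline of later breaths; classification is skipped when fewer than
#' `min_baseline` eligible breaths are available within `lookback_s`.
#'
#' @param breaths a breath table from [segment_breaths()].
#' @param epochs optional sleep-epoch table from [score_epochs()]; when
#'   `NULL` all breaths share one state.
#' @param ratio sigh threshold (default 2, applied inclusively).
#' @param n_baseline nominal trailing-window size in breaths (default 10).
#' @param min_baseline minimum eligible breaths required (default 5).
#' @param lookback_s maximum look-back in seconds (default 60).
#' @return a data frame of events: `kind` (`"sigh"`), `time` (breath onset),
#'   `duration` (inspiratory duration), `ratio` (peak / trailing mean),
#'   `state`.
#' @export
detect_sighs <- function(breaths, epochs = NULL, ratio = 2,
                         n_baseline = 10, min_baseline = 5, lookback_s = 60) {
  n <- nrow(breaths)
  if (n == 0L) return(resp_event_frame())
  st <- breath_state_vec(breaths, epochs)
  is_sigh <- logical(n)
  rat <- rep(NA_real_, n)
  not_sigh <- rep(TRUE, n)
  for (i in seq_len(n)) {
    m <- trailing_baseline(i, breaths$onset, breaths$peak, not_sigh, st,
                           n_baseline, min_baseline, lookback_s)
    if (is.finite(m) && m > 0 && breaths$peak[i] >= ratio * m) {
      is_sigh[i] <- TRUE
      not_sigh[i] <- FALSE
      rat[i] <- breaths$peak[i] / m
    }
  }
  k <- which(is_sigh)
  resp_event_frame(rep("sigh", length(k)), breaths$onset[k],
                   breaths$insp_duration[k], rat[k], st[k])
}

#' Detect apneas and post-sigh apneas in a breath sequence
#'
#' A breathing pause is an apnea when the respiratory cycle length (period,
#' onset-to-next-onset) is at least `ratio` (default 2.5, inclusive) times
#' the mean period of the preceding 10 same-state breaths. Periods of breaths
#' flagged as sighs are excluded from the trailing baseline. An apnea whose
#' onset (the offset of the breath preceding the pause) falls within
#' `postsigh_s` seconds after a sigh's offset is re-labelled
#' `postsigh_apnea`; spontaneous apnea counts exclude those.
#'
#' @inheritParams detect_sighs
#' @param sighs the sigh table from [detect_sighs()] (must be computed
#'   first); `NULL` means no sighs.
#' @param ratio apnea threshold on the period ratio (default 2.5, inclusive).
#' @param postsigh_s post-sigh window in seconds (default 8, one-sided after
#'   the sigh offset, inclusive).
#' @return a data frame of events: `kind` (`"apnea"` or `"postsigh_apnea"`),
#'   `time` (pause start), `duration` (the long period), `ratio`
#'   (period / trailing mean), `state`.
#' @export
detect_apneas <- function(breaths, epochs = NULL, sighs = NULL, ratio = 2.5,
                          n_baseline = 10, min_baseline = 5, lookback_s = 60,
                          postsigh_s = 8) {
  n <- nrow(breaths)
  if (n == 0L) return(resp_event_frame())
  st <- breath_state_vec(breaths, epochs)
  sigh_breath <- rep(FALSE, n)
  sigh_off <- numeric(0)
  if (!is.null(sighs) && nrow(sighs)) {
    sigh_breath <- breaths$onset %in% sighs$time
    sigh_off <- sighs$time + sighs$duration
  }
  kind <- character(0); tm <- dur <- rat <- numeric(0); stv <- character(0)
  for (i in seq_len(n)) {
    p <- breaths$period[i]
    if (!is.finite(p)) next
    m <- trailing_baseline(i, breaths$onset, breaths$period, !sigh_breath,
                           st, n_baseline, min_baseline, lookback_s)
    if (!is.finite(m) || m <= 0) next
    if (p >= ratio * m) {
      pause_start <- breaths$offset[i]
      k <- "apnea"
      if (length(sigh_off) &&
          any(pause_start - sigh_off >= 0 & pause_start - sigh_off <= postsigh_s))
        k <- "postsigh_apnea"
      kind <- c(kind, k); tm <- c(tm, pause_start); dur <- c(dur, p)
      rat <- c(rat, p / m); stv <- c(stv, st[i])
    }
  }
  resp_event_frame(kind, tm, dur, rat, stv)
}

#' Summarize breathing over a segment
#'
#' Computes the five per-segment respiratory metrics over breaths whose onset
#' falls in `segment`: mean frequency, coefficient of variation of
#' instantaneous frequency (CVf = SD/mean), normalized amplitude (mean peak
#' divided by the animal's baseline mean sigh amplitude), mean inspiratory
#' duration, and normalized burst area. Amplitude normalization to the
#' within-animal baseline sigh amplitude makes EMG amplitudes comparable
#' across animals despite electrode-placement differences.
#'
#' @param breaths a breath table from [segment_breaths()].
#' @param segment numeric `c(start, end)` in s; must be 60-180 s long unless
#'   `allow_any_length = TRUE`.
#' @param baseline_sigh_amp mean sigh peak amplitude during the preseizure
#'   baseline (> 0), the within-animal normalizer.
#' @param allow_any_length override the segment-length check.
#' @return a one-row data frame: `seg_start`, `seg_end`, `n_breaths`,
#'   `mean_freq`, `cv_freq`, `norm_amp`, `mean_insp_dur`, `mean_area_norm`,
#'   `insufficient`. Segments with fewer than 10 breaths are returned with
#'   `insufficient = TRUE` and `NA` metrics rather than silently.
#' @export
segment_summary <- function(breaths, segment, baseline_sigh_amp,
                            allow_any_length = FALSE) {
  segment <- as.numeric(segment)
  stopifnot(length(segment) == 2L, segment[2L] > segment[1L])
  len <- segment[2L] - segment[1L]
  if (!allow_any_length && (len < 60 || len > 180))
    stop("segment_summary: segment length must be 60-180 s ",
         "(set allow_any_length = TRUE to override)")
  if (!is.finite(baseline_sigh_amp) || baseline_sigh_amp <= 0)
    stop("segment_summary: baseline_sigh_amp must be positive")
  b <- breaths[breaths$onset >= segment[1L] & breaths$onset < segment[2L], ,
               drop = FALSE]
  out <- data.frame(seg_start = segment[1L], seg_end = segment[2L],
                    n_breaths = nrow(b), mean_freq = NA_real_,
                    cv_freq = NA_real_, norm_amp = NA_real_,
                    mean_insp_dur = NA_real_, mean_area_norm = NA_real_,
                    insufficient = TRUE)
  if (nrow(b) < 10L) return(out)
  f <- b$inst_freq[is.finite(b$inst_freq)]
  out$mean_freq <- mean(f)
  out$cv_freq <- stats::sd(f) / mean(f)
  out$norm_amp <- mean(b$peak) / baseline_sigh_amp
  out$mean_insp_dur <- mean(b$insp_duration)
  out$mean_area_norm <- mean(b$area) / baseline_sigh_amp
  out$insufficient <- FALSE
  out
}

#' Breathing-frequency z-scores against a preseizure baseline
#'
#' Each frequency sample is expressed in SD units relative to the same
#' animal's mean breathing frequency over a (nominally 6 h) preseizure
#' baseline window: `z = (sample - baseline mean) / baseline SD`. Samples at
#' least 1 SD (and 2 SD) below baseline are flagged, the markers used to
#' identify consistent slowing of breathing before PEA/death.
#'
#' @param samples data frame with columns `time` (s) and `freq` (breaths/s),
#'   e.g. hourly 1 min samples.
#' @param baseline numeric `c(start, end)` of the baseline window in s; must
#'   contain at least 3 samples.
#' @return `samples` with added columns `z`, `below_1sd` (`z <= -1`) and
#'   `below_2sd` (`z <= -2`).
#' @export
frequency_zscore <- function(samples, baseline) {
  stopifnot(all(c("time", "freq") %in% names(samples)),
            length(baseline) == 2L)
  bl <- samples$freq[samples$time >= baseline[1L] &
                       samples$time < baseline[2L]]
  if (length(bl) < 3L)
    stop("frequency_zscore: baseline must contain at least 3 samples")
  m <- mean(bl); s <- stats::sd(bl)
  if (!is.finite(s) || s <= 0)
    stop("frequency_zscore: baseline SD is zero")
  out <- samples
  out$z <- (samples$freq - m) / s
  out$below_1sd <- out$z <= -1
  out$below_2sd <- out$z <= -2
  out
}

#' Select the most stable breathing segment in a window
#'
#' Scans candidate subintervals of the given length (stepping by `step_s`)
#' and returns the one with the lowest CVf of instantaneous breathing
#' frequency, excluding candidates that overlap movement or detected
#' respiratory events or contain fewer than 10 breaths. Ties go to the
#' earliest candidate. This is the automated stand-in for manually choosing
#' "periods of stable breathing" for the hourly 1-3 min segments.
#'
#' @param breaths a breath table from [segment_breaths()].
#' @param window numeric `c(start, end)`: the search window in s.
#' @param length_s desired segment length in s (60-180, default 120).
#' @param movement optional [movement_mask()].
#' @param events optional event table with `time` and `duration` columns
#'   (e.g. rbind of apnea and sigh events) to exclude.
#' @param step_s candidate step in s (default 10).
#' @return numeric `c(start, end)` of the selected segment, or `NULL` when no
#'   eligible subinterval exists.
#' @export
select_stable_segment <- function(breaths, window, length_s = 120,
                                  movement = NULL, events = NULL,
                                  step_s = 10) {
  window <- as.numeric(window)
  stopifnot(length(window) == 2L)
  if (length_s < 60 || length_s > 180)
    stop("select_stable_segment: length_s must be 60-180 s")
  if (window[2L] - window[1L] < length_s)
    stop("select_stable_segment: window shorter than requested length")
  cand <- seq(window[1L], window[2L] - length_s, by = step_s)
  ev_iv <- if (!is.null(events) && nrow(events))
    intervals(events$time, events$time + events$duration) else NULL
  best <- NULL; best_cv <- Inf
  for (s in cand) {
    e <- s + length_s
    if (any(overlaps_intervals(s, e, movement))) next
    if (any(overlaps_intervals(s, e, ev_iv))) next
    f <- breaths$inst_freq[breaths$onset >= s & breaths$onset < e]
    f <- f[is.finite(f)]
    if (length(f) < 10L) next
    cv <- stats::sd(f) / mean(f)
    if (is.finite(cv) && cv < best_cv - 1e-12) {
      best_cv <- cv; best <- c(s, e)
    }
  }
  best
}
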