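#' Detect electrographic seizures in cortical EEG
#'
#' Seizures are abrupt increases in both amplitude and frequency: maximal
#' intervals where the amplitude envelope of the 1-50 Hz band exceeds
#' `amp_ratio` (default 2) times a robust rolling baseline, that also show an
#' elevated spectral edge frequency relative to the preceding baseline, and
#' that last longer than `min_dur_s` (default 10 s, strict). Intervals
#' separated by less than `merge_gap_s` are merged before the duration test.
#'
#' The envelope is the rectified band-passed signal smoothed over 1 s
#' (zero-phase). The baseline is a rolling median of the envelope over
#' `baseline_s`, computed in two passes: samples above threshold on the first
#' pass are excluded (held at the last baseline value) before the second, so
#' the events themselves do not inflate their own baseline.
#'
#' @param eeg the EEG [time_series()].
#' @param amp_ratio envelope/baseline detection ratio (default 2, strict >).
#' @param min_dur_s minimum event duration in s (default 10; events must be
#'   strictly longer).
#' @param merge_gap_s events closer than this are merged (default 5).
#' @param baseline_s rolling-baseline width in s (default 300; wide
#'   enough that a multi-minute event cannot capture the median).
#' @param band analysis band in Hz (default `c(1, 50)`).
#' @param freq_ratio required elevation of the 95% spectral edge frequency
#'   within the event relative to the preceding baseline (default 1.5); set
#'   to 0 to disable the frequency criterion.
#' @return a data frame: `start`, `end`, `duration`, `peak_ratio` (maximum
#'   envelope/baseline ratio inside the event).
#' @export
detect_seizures <- function(eeg, amp_ratio = 2, min_dur_s = 10,
                            merge_gap_s = 5, baseline_s = 300,
                            band = c(1, 50), freq_ratio = 1.5) {
  stopifnot(inherits(eeg, "time_series"))
  if (ts_duration(eeg) <= baseline_s)
    stop("detect_seizures: recording shorter than the baseline window")
  rate <- eeg$rate
  xb <- zp_bandpass(eeg$samples, rate, band[1], band[2], order = 2)
  env <- centered_mean(abs(xb), round(rate))

  ## decimate envelope to ~10 Hz for the rolling baseline
  dec <- max(1L, as.integer(round(rate / 10)))
  env10 <- bin_means(env, dec)
  hz10 <- rate / dec
  k <- as.integer(baseline_s * hz10); if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(env10) - (1 - length(env10) %% 2L))
  base1 <- stats::runmed(env10, k, endrule = "median")
  above1 <- env10 > amp_ratio * base1
  filled <- env10
  filled[above1] <- NA
  filled <- fill_na(filled)
  base2 <- stats::runmed(filled, k, endrule = "median")
  above <- env10 > amp_ratio * base2

  iv <- runs_to_intervals(above, hz10, eeg$start)
  if (nrow(iv) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peak_ratio = numeric(0)))
  iv <- merge_close(iv, merge_gap_s)
  iv <- iv[iv$end - iv$start > min_dur_s, , drop = FALSE]
  if (nrow(iv) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peak_ratio = numeric(0)))

  ## frequency criterion + peak ratio
  keep <- logical(nrow(iv))
  pk <- numeric(nrow(iv))
  t10 <- eeg$start + (seq_along(env10) - 0.5) / hz10
  for (j in seq_len(nrow(iv))) {
    i0 <- ts_index(eeg, iv$start[j]); i1 <- ts_index(eeg, iv$end[j])
    sef_ev <- spectral_edge(xb[i0:i1], rate, 0.95, band[1], band[2])
    b0 <- max(1L, i0 - as.integer(60 * rate))
    base_seg <- xb[b0:max(b0, i0 - 1L)]
    in_ev <- t10 >= iv$start[j] & t10 < iv$end[j]
    pk[j] <- max(env10[in_ev] / base2[in_ev])
    if (freq_ratio <= 0) { keep[j] <- TRUE; next }
    sef_bl <- spectral_edge(base_seg, rate, 0.95, band[1], band[2])
    keep[j] <- is.finite(sef_ev) && is.finite(sef_bl) &&
      sef_ev >= freq_ratio * sef_bl
  }
  iv <- iv[keep, , drop = FALSE]
  data.frame(start = iv$start, end = iv$end, duration = iv$end - iv$start,
             peak_ratio = pk[keep])
}

fill_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (!length(ok)) return(rep(0, length(x)))
  idx <- findInterval(seq_along(x), ok)
  idx[idx == 0L] <- 1L
  x[ok[idx]]
}

runs_to_intervals <- function(flag, hz, start) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]; off <- ends[r$values]
  data.frame(start = start + (on - 1L) / hz, end = start + off / hz)
}

merge_close <- function(iv, gap) {
  if (nrow(iv) <= 1L) return(iv)
  s <- iv$start; e <- iv$end
  ks <- ke <- numeric(0); cs <- s[1L]; ce <- e[1L]
  for (k in seq_along(s)[-1L]) {
    if (s[k] - ce < gap) ce <- max(ce, e[k])
    else { ks <- c(ks, cs); ke <- c(ke, ce); cs <- s[k]; ce <- e[k] }
  }
  data.frame(start = c(ks, cs), end = c(ke, ce))
}

#' Measure the duration of postictal generalized EEG suppression
#'
#' EEG power (mean square of the 0.5-50 Hz band) is summarized over a 100 s
#' preictal baseline as the mean and SD of its consecutive 5 s windows; any
#' baseline samples overlapping earlier seizures or PGES are excluded.
#' Suppression persists while postictal power is depressed more than `k_sd`
#' (3) SDs below the baseline mean, and ends at the first time the 5 s
#' moving-window power reaches the exit level `mean - 3 SD` - the 5 s
#' window is what enforces "exceeded for at least 5 s": a suprathreshold
#' excursion shorter than the window cannot lift a full window above the
#' level, while one of at least the window length can. Because a boxcar
#' window crosses a power step with a lag of up to its own length, the
#' endpoint is then refined to the first crossing of a mid-level threshold
#' (suppressed level plus 15% of the baseline contrast) by a 1 s forward
#' power average near the coarse crossing; a coarse crossing with no such
#' corroborating recovery nearby is treated as a baseline fluctuation and
#' the scan continues at the next exceedance run. Duration is 0 when the
#' first fully-postictal window already meets the criterion.
#'
#' @param eeg the EEG [time_series()].
#' @param seizure one row of the [detect_seizures()] table (needs `start`,
#'   `end`), or a list with those fields.
#' @param prior_events optional interval table (`start`, `end`) of earlier
#'   seizures/PGES to exclude from the baseline.
#' @param baseline_s preictal baseline length in s (default 100).
#' @param window_s moving-window length in s (default 5).
#' @param k_sd exit criterion in baseline SDs (default 3).
#' @param guard_s dead time after the seizure end before the first window
#'   (default 1; absorbs the edge uncertainty of the detected seizure end so
#'   ictal power cannot leak into the first postictal window).
#' @param band power band in Hz (default `c(0.5, 50)`).
#' @param max_scan_s forward scan limit past the seizure end (default 600);
#'   events still suppressed there are reported censored.
#' @param baseline_lookback_s how far back eligible preictal samples may be
#'   gathered when earlier events are excluded (default 1800).
#' @param power optional precomputed per-sample power vector (the squared
#'   band-passed EEG), to avoid re-filtering when measuring many events on
#'   one recording.
#' @return a one-row data frame: `seizure_end`, `duration`, `censored`
#'   (`TRUE` when the recording ends before the exit criterion is met; the
#'   duration is then the time remaining).
#' @export
measure_pges <- function(eeg, seizure, prior_events = NULL,
                         baseline_s = 100, window_s = 5, k_sd = 3,
                         guard_s = 1, band = c(0.5, 50), power = NULL,
                         max_scan_s = 600, baseline_lookback_s = 1800) {
  stopifnot(inherits(eeg, "time_series"))
  s_start <- as.numeric(seizure$start)[1L]
  s_end <- as.numeric(seizure$end)[1L]
  rate <- eeg$rate
  p <- if (!is.null(power)) power else
    zp_bandpass(eeg$samples, rate, band[1], min(band[2], 0.45 * rate),
                order = 2)^2

  ## eligible preictal samples within a bounded lookback
  if (s_start <= eeg$start) stop("measure_pges: no preictal data")
  keep_to <- ts_index(eeg, s_start) - 1L
  lb_from <- max(1L, keep_to - as.integer(baseline_lookback_s * rate) + 1L)
  reg <- lb_from:keep_to
  reg_t <- eeg$start + (reg - 1L) / rate
  ok <- rep(TRUE, length(reg))
  if (!is.null(prior_events) && nrow(prior_events)) {
    for (k in seq_len(nrow(prior_events)))
      ok[reg_t >= prior_events$start[k] & reg_t < prior_events$end[k]] <- FALSE
  }
  elig <- reg[ok]
  need <- as.integer(baseline_s * rate)
  if (length(elig) < need)
    stop("measure_pges: insufficient preictal baseline (need ", baseline_s,
         " s of eligible EEG)")
  elig <- elig[(length(elig) - need + 1L):length(elig)]
  wlen <- as.integer(window_s * rate)
  nwin <- need %/% wlen
  wp <- bin_means(p[elig], wlen)[seq_len(nwin)]
  b_mean <- mean(wp); b_sd <- stats::sd(wp)
  exit_level <- b_mean - k_sd * b_sd

  ## trailing 5 s window power, first window fully postictal; the forward
  ## scan is bounded at max_scan_s past the seizure end
  e_idx <- ts_index(eeg, s_end + guard_s)
  n <- min(length(p), e_idx + as.integer(max_scan_s * rate))
  if (e_idx + wlen > n)
    return(data.frame(seizure_end = s_end, duration = (n - e_idx) / rate,
                      censored = TRUE))
  cs <- c(0, cumsum(p[e_idx:n]))
  nw <- n - e_idx + 1L - wlen + 1L
  pw <- (cs[(wlen + 1L):(nw + wlen)] - cs[seq_len(nw)]) / wlen
  ex <- pw >= exit_level
  if (ex[1L])
    return(data.frame(seizure_end = s_end, duration = 0, censored = FALSE))
  if (!any(ex))
    return(data.frame(seizure_end = s_end, duration = (n - e_idx) / rate,
                      censored = TRUE))
  ## The 5 s window locates recovery coarsely: its crossing lags or leads
  ## the true power step by up to the window length, and when the baseline
  ## SD is large the exit level sits close enough to the suppressed power
  ## that a window can cross it on a fluctuation alone. Each exceedance run
  ## is therefore only a candidate endpoint: it must be corroborated by a
  ## mid-level crossing of a short (0.5 s) forward power average within one
  ## window length - genuine recovery always produces one - otherwise the
  ## scan continues at the next run.
  r <- rle(ex)
  run_ends <- cumsum(r$lengths)
  run_starts <- (run_ends - r$lengths + 1L)[r$values]
  w2 <- max(2L, as.integer(1 * rate))
  duration <- NA_real_
  for (first in run_starts) {
    pre <- seq_len(first - 1L)
    p0 <- stats::median(pw[pre[!ex[pre]]])
    if (!is.finite(p0) || b_mean <= p0) break
    ## corroborating mid-level crossing: first time the 1 s forward power
    ## reaches the suppressed level plus 15% of the baseline contrast -
    ## far above what suppressed power can fluctuate to, yet low enough
    ## that recovered activity crosses it without delay
    thr2 <- p0 + 0.15 * (b_mean - p0)
    jj <- max(1L, first - wlen):min(length(cs) - w2 - 1L, first + wlen)
    q <- (cs[jj + w2] - cs[jj]) / w2
    hit <- which(q >= thr2)[1L]
    if (!is.na(hit)) {
      duration <- max(0, guard_s + (jj[hit] - 1L) / rate)
      break
    }
  }
  if (is.na(duration))
    duration <- max(0, guard_s + (run_starts[1L] - 1L) / rate +
                      window_s / 2)
  data.frame(seizure_end = s_end, duration = duration, censored = FALSE)
}

#' Detect the onset of persistent epileptiform activity (PEA)
#'
#' PEA is the transition from discrete seizures to repeated electrographic
#' seizure activity with interictal gaps shorter than 5 min and no sustained
#' return to baseline. Operationalized deterministically: the onset is the
#' start of the first seizure that begins a run of at least `min_run`
#' consecutive interictal gaps, all shorter than `max_gap_s`, with no gap of
#' `max_gap_s` or more beginning within the following `lookahead_s`.
#'
#' @param seizures the [detect_seizures()] table (sorted by start).
#' @param eeg_end recording end time in s.
#' @param max_gap_s interictal-gap threshold in s (default 300, strict <).
#' @param min_run minimum number of consecutive short gaps (default 3).
#' @param lookahead_s sustained-transition horizon in s (default 1800).
#' @return the PEA onset time in s, or `NULL` when no such run exists.
#' @export
detect_pea_onset <- function(seizures, eeg_end, max_gap_s = 300,
                             min_run = 3, lookahead_s = 1800) {
  n <- nrow(seizures)
  if (n < min_run + 1L) return(NULL)
  gaps <- seizures$start[-1L] - seizures$end[-n]   # gap i follows seizure i
  for (i in seq_len(n - min_run)) {
    run <- gaps[i:(i + min_run - 1L)]
    if (any(run >= max_gap_s)) next
    horizon <- seizures$start[i] + lookahead_s
    later <- which(seizures$end[-n] < horizon & seq_len(n - 1L) >= i)
    if (all(gaps[later] < max_gap_s)) return(seizures$start[i])
  }
  NULL
}

#' Stage a recording by daily seizure count
#'
#' Assigns each calendar day of the recording to a disease-progression stage
#' by its seizure count (0, 1, 2-3, 4-5, 6-10, 11-20 seizures per day;
#' counts above 20 are reported in the top bin), and appends the early-PEA
#' window (within 2 h of PEA onset) and late-PEA window (within 2 h of
#' death). Days at or after PEA onset are not double-labelled, and when the
#' early and late PEA windows overlap the overlap goes to late PEA.
#'
#' @param seizures the seizure table (`start`, `end`).
#' @param pea_onset PEA onset time in s, or `NULL`.
#' @param death_time death time in s, or `NULL`.
#' @param day_s length of one "day" in s (default 86400; compressed
#'   simulated courses pass the compressed stage length).
#' @param pea_window_s half-width of the PEA stage windows (default 7200).
#' @return a data frame: `label`, `start`, `end`, `n_seizures`.
#' @export
stage_recording <- function(seizures, pea_onset = NULL, death_time = NULL,
                            day_s = 86400, pea_window_s = 7200) {
  stage_end_t <- pea_onset %||% death_time
  lab <- st <- en <- cnt <- NULL
  horizon <- stage_end_t %||%
    (if (nrow(seizures)) max(seizures$end) + day_s else day_s)
  d <- 0
  while (d < horizon) {
    e <- min(d + day_s, horizon)
    if (e - d < 1) break
    k <- sum(seizures$start >= d & seizures$start < e)
    ## scale partial days to a full-day-equivalent count for binning
    k_day <- if (e - d < day_s) round(k * day_s / (e - d)) else k
    lab <- c(lab, seizure_bin(k_day))
    st <- c(st, d); en <- c(en, e); cnt <- c(cnt, k)
    d <- d + day_s
  }
  out <- data.frame(label = lab %||% character(0),
                    start = st %||% numeric(0), end = en %||% numeric(0),
                    n_seizures = cnt %||% integer(0),
                    stringsAsFactors = FALSE)
  if (!is.null(pea_onset)) {
    e_end <- pea_onset + pea_window_s
    if (!is.null(death_time)) {
      l_start <- max(death_time - pea_window_s, pea_onset)
      e_end <- min(e_end, max(l_start, pea_onset), death_time)
      if (e_end > pea_onset) {
        k <- sum(seizures$start >= pea_onset & seizures$start < e_end)
        out <- rbind(out, data.frame(label = "early_PEA", start = pea_onset,
                                     end = e_end, n_seizures = k))
      }
      k <- sum(seizures$start >= l_start & seizures$start < death_time)
      out <- rbind(out, data.frame(label = "late_PEA", start = l_start,
                                   end = death_time, n_seizures = k))
    } else {
      k <- sum(seizures$start >= pea_onset & seizures$start < e_end)
      out <- rbind(out, data.frame(label = "early_PEA", start = pea_onset,
                                   end = e_end, n_seizures = k))
    }
  }
  out
}

seizure_bin <- function(k) {
  if (k <= 0) "0"
  else if (k == 1) "1"
  else if (k <= 3) "2-3"
  else if (k <= 5) "4-5"
  else if (k <= 10) "6-10"
  else "11-20"
}
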