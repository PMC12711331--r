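#' Order the terminal events of a recording ending in death
#'
#' Determines whether terminal apnea preceded terminal asystole: the last
#' breath is the final inspiratory-burst onset in the diaphragm EMG, the last
#' heartbeat is the final contaminating ECG R-peak, and the EEG power
#' collapse is the first time broadband EEG power falls and stays below
#' `collapse_frac` (10%) of its pre-terminal baseline. The terminal breathing
#' pattern over the final 10 min is classified as `tonic_burst` (a final
#' burst with inspiratory duration more than 5 times the median),
#' `irregular_with_apneas` (two or more apneas), `declining_rate` (negative
#' frequency trend steeper than `slope_thresh`), or `mixed`; when several
#' descriptors apply the most specific wins (tonic > irregular > declining).
#'
#' @param breaths a breath table from [segment_breaths()]; the recording must
#'   end with death, i.e. contain no breaths in its final 60 s.
#' @param ecg_peaks R-peak times from [detect_ecg_peaks()] (possibly empty:
#'   the ordering flag is then `NA`, not `FALSE`).
#' @param eeg the EEG [time_series()].
#' @param apneas optional apnea table from [detect_apneas()] (used for the
#'   pattern classification).
#' @param baseline_hours EEG power baseline length in h (default 6, clipped
#'   to what the recording provides).
#' @param collapse_frac collapse threshold as a fraction of baseline power
#'   (default 0.1).
#' @param sustain_s the power must stay below threshold this long (default
#'   60; collapse persisting to the end of the recording also counts).
#' @param slope_thresh declining-rate threshold in breaths/s per s
#'   (default -0.001).
#' @return an object of class `terminal_report`: a list with `last_breath`,
#'   `last_ecg`, `eeg_collapse`, `apnea_before_asystole` and `pattern`.
#' @export
analyze_terminal <- function(breaths, ecg_peaks, eeg, apneas = NULL,
                             baseline_hours = 6, collapse_frac = 0.1,
                             sustain_s = 60, slope_thresh = -0.001) {
  stopifnot(inherits(eeg, "time_series"))
  if (nrow(breaths) == 0L)
    stop("analyze_terminal: no breaths detected")
  rec_end <- ts_end(eeg)
  last_breath <- max(breaths$onset)
  if (rec_end - last_breath < 60)
    stop("analyze_terminal: recording does not end with death ",
         "(breaths present in the final 60 s)")
  last_ecg <- if (length(ecg_peaks)) max(ecg_peaks) else NA_real_
  flag <- if (is.na(last_ecg)) NA else last_breath < last_ecg

  ## EEG power collapse: 10 s window power at 1 s steps
  xb <- zp_bandpass(eeg$samples, eeg$rate, 0.5, min(50, 0.45 * eeg$rate), 2)
  step <- as.integer(eeg$rate)
  p1 <- bin_means(xb^2, step)                  # 1 s power samples
  pw <- centered_mean(p1, 10L)
  tt <- eeg$start + seq_along(pw) - 0.5
  base_end <- max(eeg$start + 60, last_breath - 600)
  base_start <- max(eeg$start, base_end - baseline_hours * 3600)
  base_p <- mean(pw[tt >= base_start & tt < base_end])
  below <- pw < collapse_frac * base_p
  eeg_collapse <- NA_real_
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(r$values &
                  (r$lengths >= sustain_s | ends == length(below)))
  ## "falls and stays below": take the first below-run that reaches the end
  last_run <- which(r$values & ends == length(below))
  if (length(last_run)) eeg_collapse <- tt[starts[last_run[1L]]]
  else if (length(cand)) eeg_collapse <- tt[starts[cand[1L]]]

  ## terminal breathing pattern over the final 10 min of breathing
  win <- breaths[breaths$onset >= last_breath - 600, , drop = FALSE]
  med_dur <- stats::median(breaths$insp_duration)
  tonic <- nrow(win) > 0L &&
    win$insp_duration[nrow(win)] > 5 * med_dur
  n_ap <- if (!is.null(apneas) && nrow(apneas))
    sum(apneas$time >= last_breath - 600 & apneas$time <= last_breath) else 0L
  irregular <- n_ap >= 2L
  declining <- FALSE
  f <- win[is.finite(win$inst_freq), , drop = FALSE]
  if (nrow(f) >= 5L) {
    slope <- stats::coef(stats::lm(inst_freq ~ onset, data = f))[2L]
    declining <- is.finite(slope) && slope < slope_thresh
  }
  pattern <- if (tonic) "tonic_burst"
  else if (irregular) "irregular_with_apneas"
  else if (declining) "declining_rate"
  else "mixed"

  structure(list(last_breath = last_breath, last_ecg = last_ecg,
                 eeg_collapse = eeg_collapse,
                 apnea_before_asystole = flag, pattern = pattern),
            class = "terminal_report")
}

#' @export
print.terminal_report <- function(x, ...) {
  cat("<terminal_report>\n")
  cat(sprintf("  last breath : %.2f s\n", x$last_breath))
  cat(sprintf("  last ECG    : %s\n",
              if (is.na(x$last_ecg)) "none detected" else
                sprintf("%.2f s", x$last_ecg)))
  cat(sprintf("  EEG collapse: %s\n",
              if (is.na(x$eeg_collapse)) "not reached" else
                sprintf("%.0f s", x$eeg_collapse)))
  cat(sprintf("  apnea before asystole: %s\n",
              if (is.na(x$apnea_before_asystole)) "indeterminate" else
                x$apnea_before_asystole))
  cat(sprintf("  pattern: %s\n", x$pattern))
  invisible(x)
}
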