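#' Score sleep/wake state in 10 s epochs
#'
#' Epochs tile the recording without overlap. Each epoch gets exactly one
#' state, assigned by priority: epochs at or after PEA onset are `OTH`
#' (sleep state cannot be determined during PEA); then epochs overlapping a
#' detected seizure are `SEIZ`; then PGES epochs; then movement epochs
#' (`MVM`); remaining epochs are scored spectrally. The spectral rule uses
#' per-epoch band powers from a one-segment periodogram: `delta` = 0.5-4 Hz,
#' `theta` = 4.5-8 Hz. NREM requires delta/theta >= `r_nrem`, EEG amplitude
#' at least `a_nrem` times the recording median epoch RMS (high-amplitude
#' slow activity) and tonic EMG at most `m_max` times its recording median
#' (minimal EMG activity); REM/inactive wake (merged, since nuchal EMG is
#' unavailable to separate them) requires theta/delta >= `r_rem`; anything
#' else is `OTH`.
#'
#' @param eeg the EEG [time_series()].
#' @param emg_integrated the [rectify_integrate()] EMG trace (used for the
#'   tonic-EMG gate); may be `NULL` to disable that gate.
#' @param movement optional [movement_mask()].
#' @param seizures optional [detect_seizures()] table.
#' @param pges optional PGES table with `start` (= seizure end) and
#'   `duration` columns.
#' @param pea_onset optional PEA onset time in s.
#' @param epoch_s epoch length in s (default 10).
#' @param r_nrem,r_rem band-ratio thresholds (defaults 1.5 and 1.2).
#' @param a_nrem NREM amplitude gate relative to the recording median epoch
#'   RMS (default 0.9).
#' @param m_max NREM tonic-EMG gate relative to the recording median epoch
#'   EMG level (default 3).
#' @return a data frame of epochs: `start`, `end`, `state` (one of `MVM`,
#'   `NREM`, `REM_IW`, `SEIZ`, `PGES`, `OTH`), `delta_power`, `theta_power`.
#' @export
score_epochs <- function(eeg, emg_integrated = NULL, movement = NULL,
                         seizures = NULL, pges = NULL, pea_onset = NULL,
                         epoch_s = 10, r_nrem = 1.5, r_rem = 1.2,
                         a_nrem = 0.9, m_max = 3) {
  stopifnot(inherits(eeg, "time_series"))
  if (!is.null(emg_integrated)) {
    stopifnot(inherits(emg_integrated, "time_series"))
    if (abs(ts_duration(emg_integrated) - ts_duration(eeg)) > epoch_s)
      stop("score_epochs: EEG and EMG do not cover the same interval")
  }
  n_ep <- floor(ts_duration(eeg) / epoch_s)
  if (n_ep < 1L) stop("score_epochs: recording shorter than one epoch")
  starts <- eeg$start + (seq_len(n_ep) - 1L) * epoch_s
  ends <- starts + epoch_s

  elen <- as.integer(epoch_s * eeg$rate)
  delta <- theta <- erms <- numeric(n_ep)
  for (k in seq_len(n_ep)) {
    seg <- eeg$samples[((k - 1L) * elen + 1L):(k * elen)]
    delta[k] <- band_power(seg, eeg$rate, 0.5, 4)
    theta[k] <- band_power(seg, eeg$rate, 4.5, 8)
    erms[k] <- rms(seg)
  }
  med_rms <- stats::median(erms)

  emg_level <- rep(0, n_ep)
  med_emg <- 1
  if (!is.null(emg_integrated)) {
    mlen <- as.integer(epoch_s * emg_integrated$rate)
    for (k in seq_len(n_ep)) {
      i0 <- (k - 1L) * mlen + 1L
      i1 <- min(k * mlen, length(emg_integrated$samples))
      emg_level[k] <- stats::median(emg_integrated$samples[i0:i1])
    }
    med_emg <- stats::median(emg_level)
  }

  state <- ifelse(delta / pmax(theta, .Machine$double.eps) >= r_nrem &
                    erms >= a_nrem * med_rms &
                    emg_level <= m_max * med_emg,
                  "NREM",
                  ifelse(theta / pmax(delta, .Machine$double.eps) >= r_rem,
                         "REM_IW", "OTH"))
  state[overlaps_intervals(starts, ends, movement)] <- "MVM"
  if (!is.null(pges) && nrow(pges))
    state[overlaps_intervals(starts, ends,
                             intervals(pges$start,
                                       pges$start + pges$duration))] <- "PGES"
  if (!is.null(seizures) && nrow(seizures))
    state[overlaps_intervals(starts, ends,
                             intervals(seizures$start, seizures$end))] <- "SEIZ"
  if (!is.null(pea_onset)) state[starts >= pea_onset] <- "OTH"
  data.frame(start = starts, end = ends, state = state,
             delta_power = delta, theta_power = theta,
             stringsAsFactors = FALSE)
}

#' State of the epoch containing a time point
#'
#' Epochs are half-open, so a time exactly on an epoch boundary belongs to
#' the later epoch.
#'
#' @param epochs the [score_epochs()] table.
#' @param t time in s; must lie within the scored extent.
#' @return the state string of the containing epoch.
#' @export
state_at <- function(epochs, t) {
  stopifnot(length(t) == 1L)
  if (t < epochs$start[1L] || t >= epochs$end[nrow(epochs)])
    stop("state_at: time outside the scored recording")
  epochs$state[findInterval(t, epochs$start)]
}
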