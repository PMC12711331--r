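#' High-pass filter a raw EMG channel
#'
#' Zero-phase (forward-backward) Butterworth high-pass, the first conditioning
#' step for raw diaphragm EMG: removes DC offset, movement/baseline drift and
#' low-frequency cross-talk while leaving the broadband interference pattern
#' of inspiratory bursts intact. Zero-phase filtering keeps burst timing
#' unbiased, which matters because breath onsets feed the apnea logic.
#'
#' @param ts a raw EMG [time_series()].
#' @param cutoff_hz high-pass cutoff in Hz (default 60).
#' @param order Butterworth order before the forward-backward pass.
#' @return a filtered `time_series` of the same length and rate.
#' @export
emg_highpass <- function(ts, cutoff_hz = 60, order = 4) {
  stopifnot(inherits(ts, "time_series"))
  if (ts$rate <= 2 * cutoff_hz)
    stop("emg_highpass: sampling rate must exceed twice the cutoff")
  time_series(zp_highpass(ts$samples, ts$rate, cutoff_hz, order),
              ts$rate, ts$start, ts$label)
}

#' Rectify and integrate an EMG channel
#'
#' Absolute value followed by a trailing moving average over `window_ms`
#' (36-50 ms). The window is wide relative to the ~8 ms contaminating ECG
#' spikes, so cardiac artifacts are strongly attenuated while the ~80 ms
#' inspiratory bursts survive as smooth humps whose peak, duration and area
#' are the per-breath metrics. `output[i]` is the mean of `|input|` over the
#' trailing window (expanding at the start of the record).
#'
#' @param ts a (high-pass filtered) EMG [time_series()].
#' @param window_ms integration window in ms; must lie in \[36, 50\] unless
#'   `allow_any_window = TRUE`.
#' @param allow_any_window override the window-range check.
#' @return the rectified-integrated `time_series` (same rate and length).
#' @export
rectify_integrate <- function(ts, window_ms = 40, allow_any_window = FALSE) {
  stopifnot(inherits(ts, "time_series"))
  if (!allow_any_window && (window_ms < 36 || window_ms > 50))
    stop("rectify_integrate: window_ms outside [36, 50] ",
         "(set allow_any_window = TRUE to override)")
  w <- max(1L, round(window_ms / 1000 * ts$rate))
  out <- time_series(trailing_mean(abs(ts$samples), w), ts$rate, ts$start,
                     paste0("int.", ts$label))
  ## carried so segment_breaths() can compensate the trailing window's
  ## group delay (w/2) when stamping burst edges
  attr(out, "integration_window_s") <- w / ts$rate
  out
}

#' Segment a rectified-integrated EMG trace into breaths
#'
#' Inspiratory bursts are found where the integrated trace exceeds a robust
#' two-pass rolling-median floor baseline (width 5 s; burst samples masked
#' before the second pass) by `k_mad` times the floor-noise scale. Burst
#' edges are then extended outward to a low threshold just above the floor,
#' and the known group delay of the trailing integration window (half the
#' window, read from the `rectify_integrate()` annotation) is subtracted
#' from the time stamps, so onsets track the true burst start closely.
#' Bursts separated by less than `merge_gap_s` are merged, bursts shorter
#' than `min_dur_s` are dropped, and a burst starting within `refractory_s`
#' of the previous offset is discarded.
#'
#' @param integrated the [rectify_integrate()] output.
#' @param k_mad detection threshold in floor-noise SDs above the rolling
#'   floor baseline (default 4).
#' @param min_dur_s minimum burst duration in s (default 0.02).
#' @param refractory_s dead time after each burst offset (default 0.05).
#' @param merge_gap_s bursts closer than this are merged (default 0.03).
#' @param baseline_width_s width of the rolling-median baseline (default 5).
#' @return a data frame with one row per breath: `onset`, `offset`, `peak`,
#'   `insp_duration`, `area` (integral of the baseline-subtracted trace over
#'   the burst), `period` (onset-to-next-onset; `NA` for the last breath) and
#'   `inst_freq` (1/period).
#' @export
segment_breaths <- function(integrated, k_mad = 4, min_dur_s = 0.02,
                            refractory_s = 0.05, merge_gap_s = 0.03,
                            baseline_width_s = 5) {
  stopifnot(inherits(integrated, "time_series"))
  x <- integrated$samples
  rate <- integrated$rate
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak = numeric(0), insp_duration = numeric(0),
                      area = numeric(0), period = numeric(0),
                      inst_freq = numeric(0))
  if (length(x) < 10L) return(empty)
  ## Two-pass floor baseline: a first rolling median is contaminated by the
  ## bursts themselves (integration smears them to ~50% duty at 4 breaths/s),
  ## so samples above it by 2 MAD are masked and refilled before the second
  ## median. The result tracks the quiet inter-burst floor.
  base1 <- rolling_median_baseline(x, rate, baseline_width_s)
  s1 <- stats::mad(x - base1)
  if (s1 <= 0) s1 <- max(x - base1) / 100   # noise-free synthetic traces
  if (s1 <= 0) return(empty)
  masked <- x
  masked[x > base1 + 2 * s1] <- NA
  base <- rolling_median_baseline(fill_na(masked), rate, baseline_width_s)
  resid <- x - base
  ## floor-noise scale from the negative residual half (bursts only push up)
  neg <- resid[resid < 0]
  s_floor <- if (length(neg) > 100L) stats::median(-neg) / 0.6745 else
    stats::mad(resid)
  if (s_floor <= 0) s_floor <- s1
  thr_hi <- base + k_mad * s_floor
  ## edges extended down to just above the floor so onsets are not biased
  ## late by the trailing integration window
  thr_lo <- base + 0.75 * s_floor

  above <- x > thr_hi
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  on <- starts_i[r$values]
  off <- ends_i[r$values]

  ## extend edges to the low threshold
  below_lo <- which(x <= thr_lo)
  if (length(below_lo)) {
    pos <- findInterval(on - 1L, below_lo)
    on <- ifelse(pos == 0L, 1L, below_lo[pmax(pos, 1L)] + 1L)
    nxt <- findInterval(off, below_lo) + 1L
    off <- ifelse(nxt > length(below_lo), length(x),
                  below_lo[pmin(nxt, length(below_lo))] - 1L)
  }

  ## merge overlapping / nearly-touching bursts (vectorized grouping)
  gap_n <- merge_gap_s * rate
  cm <- cummax(off)
  grp <- cumsum(c(TRUE, on[-1L] - cm[-length(cm)] > gap_n))
  keep_on <- on[!duplicated(grp)]
  keep_off <- as.integer(tapply(off, grp, max))

  ## duration + refractory rules
  dur_ok <- (keep_off - keep_on + 1L) / rate >= min_dur_s
  keep_on <- keep_on[dur_ok]; keep_off <- keep_off[dur_ok]
  if (!length(keep_on)) return(empty)
  sel <- rep(TRUE, length(keep_on))
  last_off <- keep_off[1L]
  for (k in seq_along(keep_on)[-1L]) {
    if ((keep_on[k] - last_off) / rate < refractory_s) sel[k] <- FALSE
    else last_off <- keep_off[k]
  }
  keep_on <- keep_on[sel]; keep_off <- keep_off[sel]

  ## a trailing moving average delays every edge by half its window; undo
  ## that known group delay when the producer annotated the window
  lag <- (attr(integrated, "integration_window_s") %||% 0) / 2
  onset <- pmax(integrated$start, integrated$start + (keep_on - 1L) / rate - lag)
  offset <- integrated$start + keep_off / rate - lag
  peak <- area <- numeric(length(keep_on))
  for (k in seq_along(keep_on)) {
    seg <- keep_on[k]:keep_off[k]
    peak[k] <- max(x[seg])
    area[k] <- sum(pmax(x[seg] - base[seg], 0)) / rate
  }
  period <- c(diff(onset), NA_real_)
  data.frame(onset = onset, offset = offset, peak = peak,
             insp_duration = offset - onset, area = area,
             period = period, inst_freq = 1 / period)
}

#' Detect contaminating ECG R-peaks in raw diaphragm EMG
#'
#' The cardiac field is visible in raw diaphragm EMG as a train of narrow
#' biphasic spikes. After a zero-phase 100 Hz high-pass (which removes the
#' slow content but keeps spike energy), candidate peaks are found by a
#' robust amplitude threshold; a beat period is estimated from the candidate
#' spacing and the train is then tracked beat-by-beat through the noisy
#' burst segments by searching a window around each predicted beat time.
#' Tracking stops when several consecutive predicted beats find nothing above
#' the noise floor, which is what makes the last returned peak a usable
#' asystole time. Returns an empty vector when no plausible cardiac rhythm
#' (5-16 beats/s) is present.
#'
#' @param raw_emg the raw (unfiltered, unintegrated) EMG [time_series()].
#' @param min_rate,max_rate plausible heart-rate range in beats/s.
#' @param k_mad candidate threshold in MADs of the high-passed trace.
#' @return numeric vector of R-peak times in s (possibly empty).
#' @export
detect_ecg_peaks <- function(raw_emg, min_rate = 5, max_rate = 16,
                             k_mad = 3) {
  stopifnot(inherits(raw_emg, "time_series"))
  rate <- raw_emg$rate
  xf <- zp_highpass(raw_emg$samples, rate, min(70, 0.3 * rate), 4)
  a <- abs(xf)
  ## Floor scale from the low quantile of short-window RMS values: windows
  ## falling between bursts and between beats contain only the noise floor,
  ## so the 20% quantile is uncontaminated by either.
  wl <- max(8L, as.integer(round(0.05 * rate)))
  wrms <- sqrt(bin_means(xf^2, wl))
  if (!length(wrms)) return(numeric(0))
  floor_sd <- stats::quantile(wrms, 0.2, names = FALSE)
  if (floor_sd <= 0) return(numeric(0))
  thr <- k_mad * floor_sd
  idx <- which(a > thr)
  if (length(idx) < 10L) return(numeric(0))

  ## cluster supra-threshold samples into candidate peaks (40 ms separation)
  sep <- round(0.04 * rate)
  brk <- c(0L, which(diff(idx) > sep), length(idx))
  cand <- integer(length(brk) - 1L)
  for (k in seq_len(length(brk) - 1L)) {
    seg <- idx[(brk[k] + 1L):brk[k + 1L]]
    cand[k] <- seg[which.max(a[seg])]
  }
  ct <- raw_emg$start + (cand - 1L) / rate

  ## Period estimation uses only candidates clear of EMG bursts: a smoothed
  ## envelope flags burst segments, inside which the argmax of |x| is noise,
  ## not the R-peak. Spacings between the remaining (quiet) beats cluster at
  ## integer multiples of the beat period - bursts swallow intermediate
  ## beats - so the period is recovered as an approximate greatest common
  ## divisor: the comb lag with the most chance-corrected multiple hits.
  env <- centered_mean(a, wl)
  env_floor <- stats::quantile(env, 0.2, names = FALSE)
  masked_i <- env[cand] > 3 * env_floor
  qct <- ct[!masked_i]
  if (length(qct) < 10L) qct <- ct
  d <- diff(qct)
  d <- d[d >= 0.8 / max_rate & d <= 6.5 / min_rate]
  if (length(d) < 8L) return(numeric(0))
  pgrid <- seq(1 / max_rate, 1 / min_rate, by = 0.002)
  tol <- 0.008
  score <- vapply(pgrid, function(p) {
    k <- pmax(1, round(d / p))
    hits <- sum(abs(d - k * p) < tol & k <= 6)
    hits - length(d) * 2 * tol / p      # chance hits at this comb density
  }, numeric(1))
  p0 <- pgrid[which.max(score)]
  k <- pmax(1, round(d / p0))
  ok <- abs(d - k * p0) < tol & k <= 6
  if (sum(ok) < 5L) return(numeric(0))
  period <- stats::median(d[ok] / k[ok])
  if (period < 1 / max_rate || period > 1 / min_rate) return(numeric(0))

  ## Track the rhythm forward through bursts. Predictions advance on a
  ## near-rigid grid; the grid re-anchors on accepted peaks in quiet
  ## (non-burst) regions - those are genuine beats - while in-burst maxima
  ## only confirm the beat count and cannot drag the phase. A first pass
  ## refines the period from quiet beat spacings; the second pass tracks
  ## with the refined period.
  accept_thr <- 3 * floor_sd
  quiet_s <- env <= 3 * env_floor
  n <- length(a)
  track <- function(period, t0) {
    peaks <- numeric(ceiling(ts_duration(raw_emg) / period) + 16L)
    conf <- numeric(length(peaks))
    peaks[1L] <- t0
    np <- 1L; nc <- 0L
    t_prev <- t0
    misses <- 0L
    repeat {
      t_pred <- t_prev + period
      w0 <- max(1L, round((t_pred - 0.35 * period - raw_emg$start) * rate))
      w1 <- min(n, round((t_pred + 0.35 * period - raw_emg$start) * rate))
      if (w0 >= n || w1 <= w0) break
      seg <- w0:w1
      j <- seg[which.max(a[seg])]
      if (a[j] > accept_thr) {
        tp <- raw_emg$start + (j - 1L) / rate
        np <- np + 1L
        peaks[np] <- tp
        if (quiet_s[j]) {
          nc <- nc + 1L
          conf[nc] <- tp
          t_prev <- tp
        } else {
          t_prev <- t_pred
        }
        misses <- 0L
      } else {
        misses <- misses + 1L
        t_prev <- t_pred
        if (misses >= 5L) break
      }
    }
    list(peaks = peaks[seq_len(np)], conf = conf[seq_len(nc)])
  }
  t0 <- qct[1L]
  pass1 <- track(period, t0)
  if (length(pass1$conf) >= 10L) {
    d2 <- diff(pass1$conf)
    kk <- pmax(1, round(d2 / period))
    ok <- abs(d2 / kk - period) < 0.2 * period
    if (sum(ok) >= 5L) period <- stats::median(d2[ok] / kk[ok])
  }
  pass2 <- track(period, t0)
  peaks <- pass2$peaks
  np <- length(peaks)
  ## trim trailing low-amplitude accepts: after asystole the tracker can
  ## coast onto bare noise maxima for a few beats before it gives up
  pi_ <- pmin(pmax(round((peaks - raw_emg$start) * rate) + 1L, 1L), n)
  while (np > 1L && a[pi_[np]] < 4.5 * floor_sd) np <- np - 1L
  peaks <- peaks[seq_len(np)]

  ## Sanity: a real cardiac train fills most predicted beats, keeps beating
  ## between bursts, and its quiet-region peaks stand well above the noise
  ## floor - burst noise alone fails at least one of these.
  span <- peaks[np] - peaks[1L]
  if (span <= 0 || np / (span / period) < 0.7) return(numeric(0))
  rate_obs <- (np - 1L) / span
  if (rate_obs < min_rate || rate_obs > max_rate) return(numeric(0))
  conf <- pass2$conf
  if (length(conf) < 0.3 * np) return(numeric(0))
  ci <- pmin(pmax(round((conf - raw_emg$start) * rate) + 1L, 1L), n)
  if (stats::median(a[ci]) < 4.5 * floor_sd) return(numeric(0))
  peaks
}
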