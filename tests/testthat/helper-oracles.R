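## Brute-force reference implementations and small fixture builders shared
## across the suite. The oracles deliberately use naive scans, independent of
## the vectorized package code they check.

## naive trailing moving average of |x| (O(n*w))
oracle_rectify_integrate <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(abs(x[max(1L, i - w + 1L):i]))
  out
}

## O(n^2)-style trailing-window sigh scan: for each breath walk back over
## same-state non-sigh breaths (<= 60 s), mean of up to 10 peaks, >= 5 needed
oracle_sighs <- function(breaths, states = NULL, ratio = 2,
                         n_baseline = 10, min_baseline = 5, lookback = 60) {
  n <- nrow(breaths)
  st <- states %||% rep("ALL", n)
  is_sigh <- logical(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (j in rev(seq_len(i - 1L))) {
      if (breaths$onset[i] - breaths$onset[j] > lookback) break
      if (st[j] == st[i] && !is_sigh[j]) vals <- c(vals, breaths$peak[j])
      if (length(vals) == n_baseline) break
    }
    if (length(vals) >= min_baseline &&
        breaths$peak[i] >= ratio * mean(vals)) is_sigh[i] <- TRUE
  }
  is_sigh
}

oracle_apneas <- function(breaths, states = NULL, is_sigh = NULL,
                          ratio = 2.5, n_baseline = 10, min_baseline = 5,
                          lookback = 60) {
  n <- nrow(breaths)
  st <- states %||% rep("ALL", n)
  is_sigh <- is_sigh %||% rep(FALSE, n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (!is.finite(breaths$period[i])) next
    vals <- c()
    for (j in rev(seq_len(i - 1L))) {
      if (breaths$onset[i] - breaths$onset[j] > lookback) break
      if (st[j] == st[i] && !is_sigh[j] && is.finite(breaths$period[j]))
        vals <- c(vals, breaths$period[j])
      if (length(vals) == n_baseline) break
    }
    if (length(vals) >= min_baseline &&
        breaths$period[i] >= ratio * mean(vals)) flag[i] <- TRUE
  }
  flag
}

## brute-force PGES endpoint scan: every sample a candidate exit, explicit
## window sums, same exit level and boxcar-lag refinement definition
oracle_pges_duration <- function(p, rate, s_start, s_end, baseline_s = 100,
                                 window_s = 5, k_sd = 3, guard_s = 1) {
  keep_to <- floor(s_start * rate)
  need <- baseline_s * rate
  stopifnot(keep_to >= need)
  bl <- p[(keep_to - need + 1L):keep_to]
  wlen <- window_s * rate
  wp <- sapply(seq_len(need %/% wlen),
               function(j) mean(bl[((j - 1L) * wlen + 1L):(j * wlen)]))
  L <- mean(wp) - k_sd * sd(wp)
  m <- mean(wp)
  e_idx <- floor((s_end + guard_s) * rate) + 1L
  S <- cumsum(c(0, p))
  w2 <- as.integer(1 * rate)
  pw_at <- function(i) (S[i + wlen] - S[i]) / wlen
  if (pw_at(e_idx) >= L) return(0)
  ## per-sample endpoint scan; each coarse exceedance run must be
  ## corroborated by a nearby 0.5 s mid-level crossing, else scanning
  ## continues at the next run
  pw_hist <- numeric(0)
  nh <- 0L
  first_run <- NA_integer_
  i <- e_idx
  i_max <- length(p) - wlen + 1L
  while (i <= i_max) {
    pwi <- pw_at(i)
    if (pwi < L) {
      nh <- nh + 1L
      pw_hist[nh] <- pwi
      i <- i + 1L
      next
    }
    ## entering an exceedance run at i
    if (is.na(first_run)) first_run <- i
    p0 <- median(pw_hist)
    if (!is.finite(p0) || m <= p0) break
    thr2 <- p0 + 0.15 * (m - p0)
    i_lo <- max(e_idx, i - wlen)
    i_hi <- min(i + wlen, length(p) - w2)
    for (i2 in i_lo:i_hi) {
      if (mean(p[i2:(i2 + w2 - 1L)]) >= thr2)
        return(max(0, guard_s + (i2 - e_idx) / rate))
    }
    ## no corroboration: skip past this run
    while (i <= i_max && pw_at(i) >= L) i <- i + 1L
  }
  if (is.na(first_run)) return(NA_real_)
  max(0, guard_s + (first_run - e_idx) / rate + window_s / 2)
}

## fraction of reference events matched by a detection within tol seconds
match_sensitivity <- function(detected, reference, tol) {
  if (!length(reference)) return(NA_real_)
  mean(vapply(reference, function(t) any(abs(detected - t) <= tol),
              logical(1)))
}

match_precision <- function(detected, reference, tol) {
  if (!length(detected)) return(NA_real_)
  mean(vapply(detected, function(t) any(abs(reference - t) <= tol),
              logical(1)))
}

interval_iou <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- max(a1, b1) - min(a0, b0)
  inter / union
}

## synthetic breath table with exact arithmetic (no signal processing)
make_breath_table <- function(onsets, peaks = NULL, insp = 0.08) {
  n <- length(onsets)
  peaks <- peaks %||% rep(1, n)
  period <- c(diff(onsets), NA_real_)
  data.frame(onset = onsets, offset = onsets + insp, peak = peaks,
             insp_duration = rep(insp, n), area = peaks * insp,
             period = period, inst_freq = 1 / period)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
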