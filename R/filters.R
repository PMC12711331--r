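## Shared filtering / smoothing primitives.
## All user-facing filters are zero-phase (forward-backward Butterworth) so
## event times derived from filtered traces are not biased by group delay.

zp_highpass <- function(x, rate, cutoff, order = 4) {
  bt <- signal::butter(order, cutoff / (rate / 2), type = "high")
  ## removing the mean first makes DC rejection exact and shrinks the
  ## forward-backward edge transients
  signal::filtfilt(bt, x - mean(x))
}

zp_bandpass <- function(x, rate, low, high, order = 2) {
  high <- min(high, 0.99 * rate / 2)
  bt <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  signal::filtfilt(bt, x)
}

## Trailing moving mean with an expanding start-up window: out[i] is the mean
## of x[max(1, i-w+1) .. i]. O(n) via cumulative sums.
trailing_mean <- function(x, w) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  w <- min(as.integer(w), n)
  cs <- cumsum(x)
  out <- cs / seq_len(n)
  if (n > w) {
    i <- (w + 1L):n
    out[i] <- (cs[i] - cs[i - w]) / w
  }
  out
}

## Centered moving mean (zero-phase smoothing), edges use available samples.
centered_mean <- function(x, w) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  w <- min(as.integer(w), n)
  h <- w %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Robust slow baseline: rolling median of width width_s seconds, computed on
## a decimated copy (target_hz) and linearly interpolated back. runmed on the
## full-rate trace would be needlessly slow for multi-hour recordings.
rolling_median_baseline <- function(x, rate, width_s = 5, target_hz = 100) {
  n <- length(x)
  dec <- max(1L, as.integer(round(rate / target_hz)))
  xd <- x[seq(1L, n, by = dec)]
  k <- as.integer(width_s * rate / dec)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(xd) %% 2L == 0L) length(xd) - 1L else length(xd))
  if (k < 3L) return(rep(stats::median(x), n))
  bd <- stats::runmed(xd, k, endrule = "median")
  stats::approx(seq(1L, n, by = dec), bd, xout = seq_len(n), rule = 2)$y
}

## Bin means: average x over consecutive bins of len samples (tail dropped).
bin_means <- function(x, len) {
  nb <- length(x) %/% len
  if (nb == 0L) return(numeric(0))
  .colMeans(x[seq_len(nb * len)], len, nb)
}

## Band power of a single segment by periodogram (one segment, no taper):
## mean contribution to variance from frequencies in [f1, f2].
band_power <- function(x, rate, f1, f2) {
  n <- length(x)
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))^2 / n^2
  fr <- (seq_len(n) - 1) * rate / n
  keep <- fr >= f1 & fr <= f2 & fr <= rate / 2
  2 * sum(sp[keep])
}

## Spectral edge frequency: smallest f below which `q` of the band power
## in [f1, f2] lies.
spectral_edge <- function(x, rate, q = 0.95, f1 = 0.5, f2 = 50) {
  n <- length(x)
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_len(n) - 1) * rate / n
  keep <- which(fr >= f1 & fr <= f2 & fr <= rate / 2)
  if (length(keep) < 2L) return(NA_real_)
  cum <- cumsum(sp[keep])
  fr[keep[which(cum >= q * cum[length(cum)])[1L]]]
}

rms <- function(x) sqrt(mean(x^2))
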