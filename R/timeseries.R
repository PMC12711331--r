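#' Uniformly sampled signal channel
#'
#' The substrate of every detector in the package: one channel of uniformly
#' sampled data with a sampling rate and a recording-relative start time.
#' All times in the package are 0-based seconds from recording start and all
#' intervals are half-open `[start, end)`; sample `i` (1-based) covers
#' `[start + (i-1)/rate, start + i/rate)`.
#'
#' @param samples numeric vector of finite sample values (arbitrary units).
#' @param rate sampling rate in Hz (> 0).
#' @param start recording-relative start time in seconds.
#' @param label channel name, e.g. `"EEG"` or `"DiaEMG"`.
#' @return an object of class `time_series`.
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1/500)), rate = 500)
#' ts_duration(ts)
#' @export
time_series <- function(samples, rate, start = 0, label = "") {
  if (!is.numeric(samples)) stop("time_series: samples must be numeric")
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("time_series: rate must be a single positive number")
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("time_series: samples must all be finite")
  structure(
    list(label = as.character(label)[1L], rate = as.numeric(rate),
         start = as.numeric(start)[1L], samples = as.numeric(samples)),
    class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples @ %g Hz, t = [%g, %g) s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$rate, x$start, ts_end(x)))
  invisible(x)
}

#' @export
plot.time_series <- function(x, from = NULL, to = NULL, ...) {
  w <- ts_window(x, from %||% x$start, to %||% ts_end(x))
  graphics::plot(ts_times(w), w$samples, type = "l",
                 xlab = "time (s)", ylab = x$label, ...)
  invisible(x)
}

#' Duration, end time and sample times of a channel
#' @param ts a [time_series()].
#' @return `ts_duration`: duration in s; `ts_end`: end time in s;
#'   `ts_times`: vector of sample start times in s.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

#' @rdname ts_duration
#' @export
ts_end <- function(ts) ts$start + ts_duration(ts)

#' @rdname ts_duration
#' @export
ts_times <- function(ts) ts$start + (seq_along(ts$samples) - 1) / ts$rate

#' Extract a half-open time window from a channel
#'
#' @param ts a [time_series()].
#' @param from,to window bounds in recording-relative seconds; clipped to the
#'   channel extent.
#' @return a `time_series` covering `[from, to)`.
#' @export
ts_window <- function(ts, from, to) {
  from <- max(from, ts$start); to <- min(to, ts_end(ts))
  if (to <= from) stop("ts_window: empty window")
  i0 <- ts_index(ts, from); i1 <- ts_index(ts, to - 0.5 / ts$rate)
  time_series(ts$samples[i0:i1], ts$rate,
              start = ts$start + (i0 - 1) / ts$rate, label = ts$label)
}

## 1-based index of the sample covering time t
ts_index <- function(ts, t) {
  i <- floor((t - ts$start) * ts$rate + 1e-9) + 1L
  pmin(pmax(i, 1L), length(ts$samples))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interval table constructors
#'
#' Intervals are plain data frames with numeric `start` and `end` columns,
#' half-open `[start, end)`. A movement mask is such a table whose intervals
#' must be sorted and non-overlapping.
#'
#' @param start,end interval bounds in seconds (vectors of equal length).
#' @return a data frame with columns `start`, `end`.
#' @export
intervals <- function(start = numeric(), end = numeric()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("intervals: start/end length mismatch")
  if (any(end < start)) stop("intervals: end must be >= start")
  data.frame(start = start, end = end)
}

#' @rdname intervals
#' @export
movement_mask <- function(start = numeric(), end = numeric()) {
  iv <- intervals(start, end)
  if (nrow(iv) > 1L) {
    if (is.unsorted(iv$start)) stop("movement_mask: intervals must be sorted")
    if (any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop("movement_mask: intervals must not overlap")
  }
  class(iv) <- c("movement_mask", "data.frame")
  iv
}

## does point t (or any part of [a,b)) fall inside any interval of iv?
in_intervals <- function(t, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (k in seq_len(nrow(iv)))
    out <- out | (t >= iv$start[k] & t < iv$end[k])
  out
}

overlaps_intervals <- function(a, b, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(a)))
  out <- rep(FALSE, length(a))
  for (k in seq_len(nrow(iv)))
    out <- out | (a < iv$end[k] & b > iv$start[k])
  out
}
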