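## Channel and event-table I/O.
##
## Signals travel as EDF (European Data Format; continuous, 16-bit, 1 s data
## records - the de facto interchange format for biosignal telemetry) or as
## plain CSV with one header row, a `time_s` column and one column per
## channel at a shared constant sampling interval. Physical-dimension fields
## are carried but not interpreted: all amplitudes are arbitrary units,
## consistent with within-animal normalization downstream.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

num_field <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 3, width = 1)
  pad_field(s, width)
}

#' Write a two-channel recording to EDF or CSV
#'
#' @param eeg,emg [time_series()] channels; they must share the same start
#'   time. EDF additionally requires a whole number of seconds per channel
#'   (1 s data records); CSV requires both channels to share one sampling
#'   rate.
#' @param path output path; the format is inferred from the extension
#'   (`.edf` or `.csv`) unless `format` is given.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(eeg, emg, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  stopifnot(inherits(eeg, "time_series"), inherits(emg, "time_series"))
  if (abs(eeg$start - emg$start) > 1e-9)
    stop("write_recording: channels must share a start time")
  if (format == "edf") write_edf(list(eeg, emg), path) else {
    if (abs(eeg$rate - emg$rate) > 1e-9)
      stop("write_recording: CSV requires equal channel rates")
    n <- min(length(eeg$samples), length(emg$samples))
    df <- data.frame(time_s = eeg$start + (seq_len(n) - 1) / eeg$rate,
                     a = eeg$samples[seq_len(n)], b = emg$samples[seq_len(n)])
    names(df)[2:3] <- c(eeg$label, emg$label)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

write_edf <- function(channels, path) {
  ns <- length(channels)
  dur <- vapply(channels, ts_duration, numeric(1))
  n_rec <- as.integer(round(dur[1L]))
  if (any(abs(dur - n_rec) > 1e-9))
    stop("write_edf: channels must span a whole number of seconds")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  labels <- vapply(channels, function(ch)
    if (nzchar(ch$label)) ch$label else "chan", character(1))
  spr <- vapply(channels, function(ch) as.integer(round(ch$rate)),
                integer(1))
  pmin_ <- pmax_ <- numeric(ns)
  for (k in seq_len(ns)) {
    r <- max(abs(channels[[k]]$samples), 1e-12)
    r <- signif(r * 1.001, 4)
    pmin_[k] <- -r; pmax_[k] <- r
  }
  sig_hdr <- paste0(
    paste0(vapply(labels, pad_field, character(1), width = 16L),
           collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),
    paste0(rep(pad_field("a.u.", 8), ns), collapse = ""),
    paste0(vapply(pmin_, num_field, character(1)), collapse = ""),
    paste0(vapply(pmax_, num_field, character(1)), collapse = ""),
    paste0(rep(pad_field("-32768", 8), ns), collapse = ""),
    paste0(rep(pad_field("32767", 8), ns), collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),
    paste0(vapply(spr, pad_field, character(1), width = 8L), collapse = ""),
    paste0(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  dig <- vector("list", ns)
  for (k in seq_len(ns)) {
    x <- channels[[k]]$samples
    dig[[k]] <- as.integer(round((x - pmin_[k]) / (pmax_[k] - pmin_[k]) *
                                   65535 - 32768))
  }
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      i0 <- (r - 1L) * spr[k] + 1L
      writeBin(dig[[k]][i0:(i0 + spr[k] - 1L)], con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a two-channel recording from EDF or CSV
#'
#' The EEG channel is identified by a label containing "EEG" (and not
#' "EMG"); the EMG channel by a label containing "EMG". CSV files must have
#' one header row with a `time_s` column and a constant sampling interval
#' (tolerance 1e-6 s).
#'
#' @param path input path.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return a list with elements `eeg`, `emg` ([time_series()]) and
#'   `movement` (`NULL`; movement masks travel separately as interval CSVs).
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("read_recording: file not found: ", path)
  chans <- if (format == "edf") read_edf(path) else read_signals_csv(path)
  labs <- vapply(chans, function(ch) toupper(ch$label), character(1))
  i_emg <- which(grepl("EMG", labs))[1L]
  i_eeg <- which(grepl("EEG", labs) & !grepl("EMG", labs))[1L]
  if (is.na(i_eeg)) stop("read_recording: no EEG channel found")
  if (is.na(i_emg)) stop("read_recording: no EMG channel found")
  list(eeg = chans[[i_eeg]], emg = chans[[i_emg]], movement = NULL)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 256L)
  if (length(hdr_raw) < 256L || any(hdr_raw > as.raw(0x7e)) ||
      any(hdr_raw < as.raw(0x20)))
    stop("read_edf: corrupted or unsupported EDF header")
  hdr <- rawToChar(hdr_raw)
  if (substr(hdr, 1, 1) != "0")
    stop("read_edf: corrupted or unsupported EDF header")
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1L || is.na(n_rec))
    stop("read_edf: corrupted EDF header")
  sh <- rawToChar(readBin(con, "raw", 256L * ns))
  fld <- function(off, width, k)
    substr(sh, off + (k - 1L) * width + 1L, off + k * width)
  lab_off <- 0L; pdim_off <- ns * (16L + 80L)
  pmin_off <- pdim_off + ns * 8L; pmax_off <- pmin_off + ns * 8L
  dmin_off <- pmax_off + ns * 8L; dmax_off <- dmin_off + ns * 8L
  spr_off <- dmax_off + ns * 8L + ns * 80L
  labels <- trimws(vapply(seq_len(ns), function(k) fld(lab_off, 16L, k),
                          character(1)))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(k) fld(pmin_off, 8L, k),
                             character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(k) fld(pmax_off, 8L, k),
                             character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(k) fld(dmin_off, 8L, k),
                             character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(k) fld(dmax_off, 8L, k),
                             character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(k) fld(spr_off, 8L, k),
                           character(1)))
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)))
    stop("read_edf: corrupted EDF signal header")
  dig <- lapply(seq_len(ns), function(k) integer(n_rec * spr[k]))
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      v <- readBin(con, "integer", spr[k], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[k]) stop("read_edf: truncated data record")
      dig[[k]][((r - 1L) * spr[k] + 1L):(r * spr[k])] <- v
    }
  }
  lapply(seq_len(ns), function(k) {
    x <- (dig[[k]] - dmin_[k]) / (dmax_[k] - dmin_[k]) *
      (pmax_[k] - pmin_[k]) + pmin_[k]
    time_series(x, spr[k] / rec_dur, 0, labels[k])
  })
}

read_signals_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L)
    stop("read_recording: CSV must have a time_s column plus channels")
  tt <- df$time_s
  if (length(tt) < 2L) stop("read_recording: CSV too short")
  dt <- diff(tt)
  if (max(abs(dt - dt[1L])) > 1e-6)
    stop("read_recording: non-uniform CSV timestamps")
  rate <- 1 / dt[1L]
  chans <- setdiff(names(df), "time_s")
  lapply(chans, function(nm) {
    if (anyNA(df[[nm]]) || !is.numeric(df[[nm]]))
      stop("read_recording: non-numeric or missing samples in column ", nm)
    time_series(df[[nm]], rate, tt[1L], nm)
  })
}

#' Build a unified event table
#'
#' Combines respiratory events, seizures and PGES into one table with a
#' `type` column, suitable for [write_events_csv()].
#'
#' @param resp optional [detect_apneas()] / [detect_sighs()] tables (rbind).
#' @param seizures optional [detect_seizures()] table.
#' @param pges optional PGES table (`start` = seizure end, `duration`).
#' @return a data frame sorted by `start_s` with columns `type`, `start_s`,
#'   `end_s`, `duration_s`, `ratio`, `state`.
#' @export
event_table <- function(resp = NULL, seizures = NULL, pges = NULL) {
  pieces <- list()
  if (!is.null(resp) && nrow(resp))
    pieces <- c(pieces, list(data.frame(
      type = resp$kind, start_s = resp$time,
      end_s = resp$time + resp$duration, duration_s = resp$duration,
      ratio = resp$ratio, state = resp$state, stringsAsFactors = FALSE)))
  if (!is.null(seizures) && nrow(seizures))
    pieces <- c(pieces, list(data.frame(
      type = "seizure", start_s = seizures$start, end_s = seizures$end,
      duration_s = seizures$end - seizures$start,
      ratio = if (is.null(seizures$peak_ratio)) NA_real_ else
        seizures$peak_ratio,
      state = NA_character_, stringsAsFactors = FALSE)))
  if (!is.null(pges) && nrow(pges))
    pieces <- c(pieces, list(data.frame(
      type = "pges", start_s = pges$start,
      end_s = pges$start + pges$duration, duration_s = pges$duration,
      ratio = NA_real_, state = NA_character_, stringsAsFactors = FALSE)))
  if (!length(pieces))
    return(data.frame(type = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      ratio = numeric(0), state = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  out[order(out$start_s), , drop = FALSE]
}

#' Write / read an event table as CSV
#'
#' One row per event; events must be sorted by start time. Times round-trip
#' losslessly well beyond 1 microsecond precision.
#'
#' @param events a data frame with at least `type` and `start_s` columns
#'   (e.g. from [event_table()]).
#' @param path CSV path.
#' @return `write_events_csv`: `path` invisibly; `read_events_csv`: the
#'   event data frame.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(is.data.frame(events),
            all(c("type", "start_s") %in% names(events)))
  if (nrow(events) > 1L && is.unsorted(events$start_s))
    stop("write_events_csv: events must be sorted by start time")
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("read_events_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("type", "start_s") %in% names(df)))
    stop("read_events_csv: not an event table")
  df
}

#' Write / read a movement mask as an interval CSV
#' @param mask a [movement_mask()].
#' @param path CSV path.
#' @return `write_movement_csv`: `path` invisibly; `read_movement_csv`: a
#'   [movement_mask()].
#' @export
write_movement_csv <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_movement_csv
#' @export
read_movement_csv <- function(path) {
  df <- utils::read.csv(path)
  movement_mask(df$start, df$end)
}
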