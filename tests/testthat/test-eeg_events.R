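test_that("seizure detection respects the >10 s duration rule", {
  ## programmed bursts of 8, 12, 9 and 20 s at 3x: only >10 s retained
  sz <- data.frame(start = c(400, 700, 1000, 1300),
                   duration = c(8, 12, 9, 20),
                   amp_ratio = 3, freq = 8)
  rec <- generate_recording(sim_config(duration = 1700, seed = 13,
                                       nrem_s = 1700, rem_s = 1,
                                       seizure_schedule = sz))
  det <- detect_seizures(rec$eeg)
  expect_equal(nrow(det), 2)
  expect_true(all(abs(det$start - c(700, 1300)) < 1))
  expect_true(all(det$duration > 10))
})

test_that("stationary recordings yield no seizure detections", {
  rec <- generate_recording(sim_config(duration = 1800, seed = 14))
  expect_equal(nrow(detect_seizures(rec$eeg)), 0)
})

test_that("programmed seizures are recovered with accurate edges", {
  sz <- data.frame(start = c(400, 900), duration = c(20, 35),
                   amp_ratio = c(3, 3.5), freq = 8)
  rec <- generate_recording(sim_config(duration = 1400, seed = 15,
                                       seizure_schedule = sz))
  det <- detect_seizures(rec$eeg)
  expect_equal(nrow(det), 2)
  expect_true(all(abs(det$start - sz$start) < 1))
  expect_true(all(abs(det$end - (sz$start + sz$duration)) < 1))
  expect_true(all(det$peak_ratio > 2))
})

test_that("PGES measurement matches programmed suppression and rules", {
  ## no suppression -> duration 0
  sz <- data.frame(start = 300, duration = 20, amp_ratio = 3, freq = 8)
  rec0 <- generate_recording(sim_config(duration = 600, seed = 16,
          nrem_s = 600, rem_s = 1, seizure_schedule = sz,
          pges_durations = 0))
  pg0 <- measure_pges(rec0$eeg, list(start = 300, end = 320))
  expect_equal(pg0$duration, 0)
  ## programmed 30 s suppression, clean recovery -> 30 +- 1 s
  rec1 <- generate_recording(sim_config(duration = 600, seed = 16,
          nrem_s = 600, rem_s = 1, seizure_schedule = sz,
          pges_durations = 30))
  pg1 <- measure_pges(rec1$eeg, detect_seizures(rec1$eeg)[1, ])
  expect_lt(abs(pg1$duration - 30), 1)
  ## insufficient preictal baseline -> labeled error
  expect_error(measure_pges(rec1$eeg, list(start = 50, end = 70)),
               "baseline")
})

test_that("a 4 s suprathreshold excursion does not end PGES; 5 s does", {
  ## constructed trace: broadband baseline, deep suppression, an excursion
  ## of just-suprathreshold power, then full recovery
  rate <- 500
  build <- function(exc_len) {
    set.seed(20)
    n <- 420 * rate
    x <- rnorm(n)                       # broadband baseline, power ~1
    supp <- function(t0, t1) {
      i <- (t0 * rate + 1):(t1 * rate)
      x[i] <<- x[i] * 0.1
    }
    supp(220, 420)                      # suppression after "seizure end" 220
    ## excursion back to baseline amplitude: suprathreshold, but a window
    ## can only be lifted above the exit level if the excursion fills it
    i <- (280 * rate + 1):((280 + exc_len) * rate)
    x[i] <- x[i] * 10                   # 0.1 -> 1.0 amplitude
    ## full recovery at 350 s
    i <- (350 * rate + 1):(420 * rate)
    x[i] <- x[i] * 10
    time_series(x, rate, label = "EEG")
  }
  eeg4 <- build(4)
  pg4 <- measure_pges(eeg4, list(start = 200, end = 220), band = c(0.5, 200))
  expect_gt(pg4$duration, 100)          # excursion did not terminate it
  eeg5 <- build(5)
  pg5 <- measure_pges(eeg5, list(start = 200, end = 220), band = c(0.5, 200))
  expect_lt(pg5$duration, 70)           # 5 s excursion ends the event
  expect_gt(pg5$duration, 50)
})

test_that("PGES equals the brute-force endpoint-scan oracle", {
  set.seed(33)
  rate <- 250
  for (case in 1:12) {
    dur_s <- sample(c(160, 200, 300), 1)
    n <- dur_s * rate
    x <- rnorm(n)
    s_start <- 105; s_end <- 110
    d <- runif(1, 5, min(40, dur_s - 130))
    i <- (round(s_end * rate) + 1):round((s_end + d) * rate)
    x[i] <- x[i] * 0.1
    eeg <- time_series(x, rate, label = "EEG")
    got <- measure_pges(eeg, list(start = s_start, end = s_end),
                        band = c(0.5, 100))
    p <- epivent:::zp_bandpass(x, rate, 0.5, min(100, 0.45 * rate), 2)^2
    want <- oracle_pges_duration(p, rate, s_start, s_end)
    expect_equal(got$duration, want, tolerance = 0.6, info = case)
    expect_lt(abs(got$duration - d), 1.5)
  }
})

test_that("deeper programmed suppression never shortens measured PGES", {
  sz <- data.frame(start = 300, duration = 20, amp_ratio = 3, freq = 8)
  durs <- c()
  for (amp in c(0.3, 0.2, 0.1, 0.05)) {
    rec <- generate_recording(sim_config(duration = 500, seed = 18,
            nrem_s = 500, rem_s = 1, seizure_schedule = sz,
            pges_durations = 40, pges_amp = amp))
    durs <- c(durs, measure_pges(rec$eeg,
                                 list(start = 300, end = 320))$duration)
  }
  expect_true(all(diff(durs) > -1))
})

test_that("PEA onset follows the sustained short-gap rule", {
  ## empty list -> absent
  none <- data.frame(start = numeric(0), end = numeric(0))
  expect_null(detect_pea_onset(none, 7200))
  ## seizures every 3 min from t0 -> onset t0
  st <- seq(1000, 7000, by = 180)
  sz <- data.frame(start = st, end = st + 30)
  expect_equal(detect_pea_onset(sz, 7200), 1000)
  ## alternating 3 / 20 min gaps -> absent (brute-force run scan agrees)
  st2 <- cumsum(c(1000, rep(c(210, 1230), 8)))
  sz2 <- data.frame(start = st2, end = st2 + 30)
  expect_null(detect_pea_onset(sz2, max(st2) + 600))
  ## gap boundary: exactly 5 min gaps do not qualify, 299 s gaps do
  st3 <- cumsum(c(1000, rep(330, 10)))      # gaps end->next start = 300
  sz3 <- data.frame(start = st3, end = st3 + 30)
  expect_null(detect_pea_onset(sz3, max(st3) + 600))
  st4 <- cumsum(c(1000, rep(329, 10)))      # gaps = 299 < 300
  sz4 <- data.frame(start = st4, end = st4 + 30)
  expect_equal(detect_pea_onset(sz4, max(st4) + 600), 1000)
})

test_that("stage labels follow the daily seizure-count bins", {
  day <- 86400
  mk <- function(counts) {
    st <- unlist(lapply(seq_along(counts), function(d)
      if (counts[d] > 0) (d - 1) * day + seq_len(counts[d]) * 1000 else
        numeric(0)))
    data.frame(start = st, end = st + 30)
  }
  sz <- mk(c(0, 1, 3, 5, 7, 15))
  stg <- stage_recording(sz, pea_onset = 6 * day, death_time = 6 * day + 3 * 3600)
  expect_equal(stg$label[1:6], c("0", "1", "2-3", "4-5", "6-10", "11-20"))
  ## PEA windows: early 2 h from onset, late 2 h before death
  expect_true("early_PEA" %in% stg$label)
  expect_true("late_PEA" %in% stg$label)
  e <- stg[stg$label == "early_PEA", ]
  l <- stg[stg$label == "late_PEA", ]
  ## death 3 h after onset: the middle hour is shared - it goes to late_PEA
  expect_equal(l$end - l$start, 7200)
  expect_equal(e$start, 6 * day)
  expect_equal(e$end, l$start)   # overlap resolved in favor of late_PEA
  ## death 1 h after PEA onset -> the whole window belongs to late_PEA
  stg2 <- stage_recording(sz, pea_onset = 6 * day,
                          death_time = 6 * day + 3600)
  expect_false("early_PEA" %in% stg2$label)
  expect_equal(stg2$end[stg2$label == "late_PEA"], 6 * day + 3600)
  ## 0 seizures throughout -> single stage "0" per day
  stg3 <- stage_recording(none <- data.frame(start = numeric(0),
                                             end = numeric(0)),
                          pea_onset = NULL, death_time = day)
  expect_true(all(stg3$label == "0"))
})
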