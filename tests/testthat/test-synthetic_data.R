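test_that("event-free baseline recording has the scheduled breath count", {
  rec <- generate_recording(sim_config(duration = 60, seed = 42))
  expect_true(abs(nrow(rec$truth$breaths) - 240) <= 1)
  expect_equal(nrow(rec$truth$sighs), 0)
  expect_equal(nrow(rec$truth$apneas), 0)
  expect_equal(nrow(rec$truth$seizures), 0)
  expect_equal(length(rec$emg$samples), 60000)
  expect_equal(length(rec$eeg$samples), 30000)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(duration = 20, seed = 7,
                    sigh_times = 8,
                    apnea_schedule = data.frame(time = 14, period_ratio = 3))
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$emg$samples, b$emg$samples)
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$truth$breaths, b$truth$breaths)
})

test_that("terminal schedule silences breaths then ECG", {
  cfg <- sim_config(duration = 120, seed = 3,
                    terminal = list(apnea_time = 60, asystole_time = 90))
  rec <- generate_recording(cfg)
  expect_equal(max(rec$truth$breaths$onset), 60)
  expect_lt(max(rec$truth$ecg_beats), 90)
  expect_gt(max(rec$truth$ecg_beats), 89)
  ## no burst energy after the terminal apnea: compare integrated EMG level
  ri <- rectify_integrate(emg_highpass(rec$emg))
  pre <- ri$samples[(20 * 1000):(50 * 1000)]
  post <- ri$samples[(95 * 1000):(115 * 1000)]
  expect_lt(max(post), max(pre) / 3)
  expect_error(sim_config(duration = 50, terminal = list(
    apnea_time = 40, asystole_time = 30)), "asystole")
})

test_that("schedules beyond the recording are rejected", {
  expect_error(sim_config(duration = 10, sigh_times = 12), "exceeds")
  expect_error(sim_config(duration = 10, apnea_schedule =
    data.frame(time = 11, period_ratio = 3)), "exceeds")
  expect_error(sim_config(duration = 10, seizure_schedule =
    data.frame(start = 5, duration = 10, amp_ratio = 3, freq = 8)),
    "exceeds")
  expect_error(sim_config(duration = 10, apnea_schedule =
    data.frame(time = 5, period_ratio = 0.9)), "period_ratio")
})

test_that("scheduled apneas appear as gaps consistent with ground truth", {
  cfg <- sim_config(duration = 120, seed = 9, apnea_schedule =
    data.frame(time = c(30, 70, 100), period_ratio = c(3, 2.8, 3.5)))
  rec <- generate_recording(cfg)
  tr <- rec$truth
  expect_equal(nrow(tr$apneas), 3)
  ## brute-force scan of ground-truth breath onsets: each scheduled apnea
  ## must be a gap >= ratio x the local mean period
  on <- tr$breaths$onset
  for (k in seq_len(nrow(tr$apneas))) {
    i <- max(which(on <= tr$apneas$time[k])) # breath before the gap
    gap <- on[i + 1] - on[i]
    local <- mean(diff(on[max(1, i - 10):i]))
    ## realized ratio wobbles with the 2% inter-breath jitter
    expect_gt(gap / local, 0.9 * tr$apneas$ratio[k])
    expect_lt(gap / local, 1.1 * tr$apneas$ratio[k])
  }
  ## and no other comparable gap exists
  gaps <- diff(on)
  expect_equal(sum(gaps > 2 * median(gaps)), 3)
})

test_that("NREM and REM blocks have the advertised spectral contrast", {
  rec <- generate_recording(sim_config(duration = 720, seed = 12))
  bl <- rec$truth$blocks
  for (k in seq_len(nrow(bl))) {
    if (bl$end[k] - bl$start[k] < 60) next
    seg <- ts_window(rec$eeg, bl$start[k] + 5, bl$end[k] - 5)
    delta <- epivent:::band_power(seg$samples, seg$rate, 0.5, 4)
    theta <- epivent:::band_power(seg$samples, seg$rate, 4.5, 8)
    if (bl$state[k] == "NREM") expect_gt(delta, theta)
    else expect_gt(theta, delta)
  }
})

test_that("disease course escalates seizures and ends in PEA + death", {
  dc <- generate_disease_course(seed = 21, stages = data.frame(
    seizures_per_day = c(0, 2, 6), hours = c(0.3, 0.3, 0.5)))
  st <- dc$truth$stages
  expect_true(all(diff(st$n_seizures) >= 0))
  expect_equal(st$n_seizures[1], 0)
  expect_false(is.null(dc$truth$pea_onset))
  ## PEA-phase gaps below the 5 min criterion
  pea_sz <- dc$truth$seizures[dc$truth$seizures$start >= dc$truth$pea_onset, ]
  if (nrow(pea_sz) > 1) {
    gaps <- pea_sz$start[-1] - pea_sz$end[-nrow(pea_sz)]
    expect_true(all(gaps < 300))
  }
  expect_false(is.null(dc$truth$terminal))
  expect_gt(dc$truth$terminal$asystole_time, dc$truth$terminal$last_breath)
  expect_error(generate_disease_course(seed = 1, stages = data.frame(
    seizures_per_day = 1, hours = 0)), "zero-length")
})
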