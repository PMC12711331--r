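test_that("high-pass removes DC and slow content, passes fast content", {
  rate <- 1000
  tt <- seq(0, 5, by = 1 / rate)[-1]
  ## constant input -> (near) zero output
  const <- time_series(rep(2, length(tt)), rate)
  out <- emg_highpass(const)
  expect_lt(max(abs(out$samples)), 1e-9 * 2)
  ## 5 Hz attenuated >= 20 dB
  slow <- time_series(sin(2 * pi * 5 * tt), rate)
  r5 <- epivent:::rms(emg_highpass(slow)$samples) /
    epivent:::rms(slow$samples)
  expect_lt(20 * log10(r5), -20)
  ## 120 Hz passed within 1 dB
  fast <- time_series(sin(2 * pi * 120 * tt), rate)
  mid <- 1000:4000   # avoid filter edge transients
  r120 <- epivent:::rms(emg_highpass(fast)$samples[mid]) /
    epivent:::rms(fast$samples[mid])
  expect_gt(20 * log10(r120), -1)
  ## rate precondition
  expect_error(emg_highpass(time_series(rnorm(100), 100)), "rate")
})

test_that("rectify-integrate matches the naive trailing-mean oracle", {
  rate <- 1000
  ## degenerate cases
  z <- rectify_integrate(time_series(rep(0, 500), rate))
  expect_true(all(z$samples == 0))
  a <- rectify_integrate(time_series(rep(0.7, 500), rate))
  expect_equal(a$samples[100:500], rep(0.7, 401), tolerance = 1e-12)
  ## seeded noise vs O(n*w) oracle, across the allowed window range
  set.seed(5)
  x <- rnorm(2000)
  for (wms in c(36, 40, 50)) {
    got <- rectify_integrate(time_series(x, rate), window_ms = wms)
    expect_equal(got$samples, oracle_rectify_integrate(x, wms),
                 tolerance = 1e-12)
  }
  ## window range enforced unless overridden
  expect_error(rectify_integrate(time_series(x, rate), window_ms = 30),
               "36")
  expect_silent(rectify_integrate(time_series(x, rate), window_ms = 30,
                                  allow_any_window = TRUE))
})

test_that("integration suppresses narrow ECG spikes without disturbing breaths", {
  rec <- generate_recording(sim_config(duration = 60, seed = 31,
                                       ecg_amp_ratio = 0))
  clean <- rec$emg
  ## add biphasic spikes: width 8 ms, amplitude 0.5x burst peak, 10/s
  rate <- clean$rate
  spiky <- clean$samples
  tw <- round(0.008 * rate)
  tmpl <- sin(2 * pi * seq_len(tw) / tw) * 0.5
  beats <- seq(0.05, 59.9, by = 0.1)
  for (b in beats) {
    i <- floor(b * rate) + 1
    spiky[i:(i + tw - 1)] <- spiky[i:(i + tw - 1)] + tmpl
  }
  ri_clean <- rectify_integrate(emg_highpass(clean))
  ri_spiky <- rectify_integrate(emg_highpass(
    time_series(spiky, rate, label = "DiaEMG")))
  ## spike peak attenuated by ~window/width in the integrated trace
  delta <- ri_spiky$samples - ri_clean$samples
  expect_lt(max(abs(delta)), 0.5 * 0.008 / 0.040 * 1.5)
  ## overall trace perturbation bounded by the analytic worst case:
  ## rectified spikes add <= A*(2/pi)*(width/window) for ~(width+window)
  ## around each beat, an RMS perturbation below a quarter of the trace RMS
  rel <- epivent:::rms(delta) / epivent:::rms(ri_clean$samples)
  expect_lt(rel, 0.25)
  ## breath segmentation unchanged in count, peaks within a few %
  b1 <- segment_breaths(ri_clean)
  b2 <- segment_breaths(ri_spiky)
  expect_equal(nrow(b2), nrow(b1))
  expect_lt(median(abs(b2$peak - b1$peak) / b1$peak), 0.05)
})

test_that("breath segmentation recovers the programmed train", {
  rec <- generate_recording(sim_config(duration = 60, seed = 1))
  b <- segment_breaths(rectify_integrate(emg_highpass(rec$emg)))
  tr <- rec$truth$breaths
  expect_true(abs(nrow(b) - nrow(tr)) <= 2)
  err <- vapply(tr$onset, function(o) min(abs(b$onset - o)), numeric(1))
  expect_lt(max(err), 0.010)
  ## flat/noise-free trace -> empty list
  flat <- time_series(rep(0.3, 5000), 1000)
  expect_equal(nrow(segment_breaths(flat)), 0)
})

test_that("breath metrics follow the onset-to-onset convention", {
  ## two clean bursts 0.25 s apart on a quiet floor
  rate <- 1000
  x <- rep(0.01, 3000)
  env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 80)))
  x[1001:1080] <- x[1001:1080] + env
  x[1251:1330] <- x[1251:1330] + env
  b <- segment_breaths(time_series(x, rate))
  expect_equal(nrow(b), 2)
  expect_equal(b$period[1], 0.25, tolerance = 0.01)
  expect_equal(b$inst_freq[1], 4, tolerance = 0.2)
  expect_true(is.na(b$period[2]))
  expect_true(all(b$peak > 0.9))
})

test_that("removing one scheduled burst lowers the detected count by one", {
  cfg1 <- sim_config(duration = 30, seed = 17)
  rec1 <- generate_recording(cfg1)
  n1 <- nrow(segment_breaths(rectify_integrate(emg_highpass(rec1$emg))))
  ## realize one apnea (a stretched gap swallows exactly one burst slot)
  cfg2 <- sim_config(duration = 30, seed = 17, apnea_schedule =
                       data.frame(time = 15, period_ratio = 2))
  rec2 <- generate_recording(cfg2)
  n2 <- nrow(segment_breaths(rectify_integrate(emg_highpass(rec2$emg))))
  expect_equal(nrow(rec1$truth$breaths) - nrow(rec2$truth$breaths),
               n1 - n2)
})

test_that("ECG peak detection counts and terminates correctly", {
  rec <- generate_recording(sim_config(duration = 30, seed = 2))
  pk <- detect_ecg_peaks(rec$emg)
  expect_true(abs(length(pk) - length(rec$truth$ecg_beats)) <= 3)
  ## zero-amplitude ECG -> empty
  rec0 <- generate_recording(sim_config(duration = 30, seed = 2,
                                        ecg_amp_ratio = 0))
  expect_length(detect_ecg_peaks(rec0$emg), 0)
  ## peaks absent after scheduled asystole
  rect <- generate_recording(sim_config(duration = 90, seed = 4,
    terminal = list(apnea_time = 40, asystole_time = 60)))
  pkt <- detect_ecg_peaks(rect$emg)
  expect_lt(max(pkt), 60.5)
  expect_gt(max(pkt), 59)
})
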