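test_that("sigh threshold is inclusive at exactly twice the trailing mean", {
  on <- seq(0, by = 0.25, length.out = 30)
  pk <- rep(1, 30)
  pk[20] <- 2.0          # exactly 2x the trailing mean
  b <- make_breath_table(on, pk)
  sg <- detect_sighs(b)
  expect_equal(sg$time, b$onset[20])
  expect_equal(sg$ratio, 2.0, tolerance = 1e-12)
  pk[20] <- 1.99
  expect_equal(nrow(detect_sighs(make_breath_table(on, pk))), 0)
  ## constant train -> no sighs
  expect_equal(nrow(detect_sighs(make_breath_table(on))), 0)
})

test_that("apnea threshold is inclusive at exactly 2.5x; 2.49x is not flagged", {
  on <- c(seq(0, by = 0.4, length.out = 20))
  on <- c(on, on[20] + 0.4 * 2.5, on[20] + 0.4 * 2.5 + 0.4)
  b <- make_breath_table(on)
  ap <- detect_apneas(b)
  expect_equal(nrow(ap), 1)
  expect_equal(ap$kind, "apnea")
  expect_equal(ap$ratio, 2.5, tolerance = 1e-9)
  expect_equal(ap$duration, 1.0, tolerance = 1e-9)
  ## 2.49x -> not flagged
  on2 <- c(seq(0, by = 0.4, length.out = 20))
  on2 <- c(on2, on2[20] + 0.4 * 2.49, on2[20] + 0.4 * 2.49 + 0.4)
  expect_equal(nrow(detect_apneas(make_breath_table(on2))), 0)
  ## uniform train -> none
  expect_equal(nrow(detect_apneas(make_breath_table(
    seq(0, by = 0.25, length.out = 50)))), 0)
})

test_that("post-sigh window boundary: within 8 s reclassifies, beyond does not", {
  build <- function(gap_after_sigh) {
    sigh_i <- 20
    on <- seq(0, by = 0.25, length.out = 120)
    sigh_off <- on[sigh_i] + 0.08
    ## breath whose offset starts the pause, exactly gap_after_sigh after
    ## the sigh offset
    pause_breath <- sigh_off + gap_after_sigh - 0.08
    on <- c(on[on <= pause_breath - 0.01], pause_breath)
    on <- c(on, pause_breath + 0.75, pause_breath + 1.0, pause_breath + 1.25)
    pk <- rep(1, length(on)); pk[sigh_i] <- 2.5
    make_breath_table(on, pk)
  }
  for (gap in c(5, 7.99, 8)) {
    b <- build(gap)
    sg <- detect_sighs(b)
    ap <- detect_apneas(b, sighs = sg)
    expect_equal(nrow(ap), 1)
    expect_equal(ap$kind, "postsigh_apnea", info = paste("gap", gap))
  }
  b <- build(9)
  ap <- detect_apneas(b, sighs = detect_sighs(b))
  expect_equal(nrow(ap), 1)
  expect_equal(ap$kind, "apnea")
})

test_that("classification is isolated within behavioral state", {
  ## NREM breaths form a slow train; interleaved REM breaths are fast.
  ## A pause that is apneic relative to the REM baseline must be judged
  ## against REM breaths only, however the NREM breaths around it look.
  ep <- data.frame(start = seq(0, 190, by = 10))
  ep$end <- ep$start + 10
  ep$state <- rep(c("NREM", "REM_IW"), length.out = nrow(ep))
  on <- sort(c(seq(0.5, 180, by = 0.4) + 0.001))
  b <- make_breath_table(on)
  st <- vapply(on, function(t) state_at(ep, t), character(1))
  sg <- detect_sighs(b, ep)
  ap1 <- detect_apneas(b, ep, sg)
  ## permute peaks of the other state: sigh/apnea calls must not change
  b2 <- b
  set.seed(1)
  rem_idx <- which(st == "REM_IW")
  b2$peak[rem_idx] <- sample(b2$peak[rem_idx])
  nrem_events_1 <- detect_sighs(b, ep)
  nrem_events_2 <- detect_sighs(b2, ep)
  expect_equal(nrem_events_1$time[nrem_events_1$state == "NREM"],
               nrem_events_2$time[nrem_events_2$state == "NREM"])
  expect_equal(nrow(ap1), 0)
})

test_that("detectors agree with the brute-force trailing-window oracle", {
  set.seed(99)
  for (case in 1:30) {
    n <- sample(c(80, 200, 500, 1500), 1)
    periods <- runif(n, 0.2, 0.3)
    ## inject pauses and big breaths at random
    pause_at <- sample(20:(n - 5), 3)
    periods[pause_at] <- periods[pause_at] * runif(3, 2, 4)
    on <- cumsum(c(0.3, periods))[1:n]
    pk <- exp(rnorm(n, 0, 0.1))
    pk[sample(20:(n - 5), 3)] <- runif(3, 2.2, 3.5)
    b <- make_breath_table(on, pk)
    sg <- detect_sighs(b)
    or_sigh <- oracle_sighs(b)
    expect_equal(sort(b$onset[or_sigh]), sort(sg$time), info = case)
    ap <- detect_apneas(b, sighs = sg)
    or_ap <- oracle_apneas(b, is_sigh = or_sigh)
    expect_equal(sort(b$offset[or_ap]),
                 sort(ap$time), info = case)
  }
  ## one large train
  set.seed(7)
  n <- 10000
  periods <- runif(n, 0.22, 0.28)
  periods[sample(n - 10, 20) + 5] <- runif(20, 0.6, 1.2)
  on <- cumsum(c(0, periods))[1:n]
  pk <- exp(rnorm(n, 0, 0.08)); pk[sample(n - 10, 15) + 5] <- 2.6
  b <- make_breath_table(on, pk)
  sg <- detect_sighs(b); or_sigh <- oracle_sighs(b)
  expect_equal(sort(b$onset[or_sigh]), sort(sg$time))
  ap <- detect_apneas(b, sighs = sg)
  or_ap <- oracle_apneas(b, is_sigh = or_sigh)
  expect_equal(sort(b$offset[or_ap]), sort(ap$time))
})

test_that("segment summaries compute the five metrics and self-normalize", {
  ## constant period p -> mean_freq = 1/p, cv = 0
  on <- seq(100, 220, by = 0.25)
  b <- make_breath_table(on, rep(2, length(on)))
  s <- segment_summary(b, c(100, 220), baseline_sigh_amp = 2)
  expect_false(s$insufficient)
  expect_equal(s$mean_freq, 4, tolerance = 1e-9)
  expect_equal(s$cv_freq, 0)
  expect_equal(s$norm_amp, 1.0)   # breaths equal baseline sighs in peak
  expect_equal(s$mean_insp_dur, 0.08)
  ## seeded irregular train: cv matches the direct formula
  set.seed(3)
  on2 <- cumsum(runif(600, 0.2, 0.3)) + 100
  b2 <- make_breath_table(on2, exp(rnorm(600, 0, 0.2)))
  s2 <- segment_summary(b2, c(100, 220), baseline_sigh_amp = 1.5)
  f <- b2$inst_freq[b2$onset >= 100 & b2$onset < 220]
  f <- f[is.finite(f)]
  expect_equal(s2$cv_freq, sd(f) / mean(f), tolerance = 1e-12)
  ## <10 breaths -> flagged insufficient, not silent
  s3 <- segment_summary(make_breath_table(seq(0, 120, by = 30)),
                        c(0, 120), 1)
  expect_true(s3$insufficient)
  expect_true(is.na(s3$mean_freq))
  ## segment length policed
  expect_error(segment_summary(b, c(0, 30), 1), "60-180")
  expect_error(segment_summary(b, c(100, 220), 0), "positive")
})

test_that("frequency z-scores flag slowing at 1 and 2 SD", {
  tt <- seq(0, 3600 * 10, by = 3600)
  ## baseline chosen so mean = 4 and SD = 0.5 exactly (z lands on the
  ## 1 and 2 SD boundaries without floating-point slop)
  base <- c(3.5, 4.5, 3.5, 4.5, 4.0)
  m <- 4; s <- 0.5
  freq <- c(base, m, m - s, m - 2 * s, m - 3 * s, m + s, m)
  z <- frequency_zscore(data.frame(time = tt, freq = freq),
                        baseline = c(0, 5 * 3600))
  expect_equal(z$z[6], 0, tolerance = 1e-12)
  expect_equal(z$z[7], -1, tolerance = 1e-12)
  expect_true(z$below_1sd[7])
  expect_false(z$below_2sd[7])
  expect_true(z$below_2sd[8])
  expect_equal(z$z, (freq - m) / s, tolerance = 1e-12)
  expect_error(frequency_zscore(data.frame(time = 1:2, freq = c(1, 2)),
                                c(0, 10)), "3 samples")
  expect_error(frequency_zscore(data.frame(time = tt, freq = rep(4, 11)),
                                c(0, 5 * 3600)), "SD")
})

test_that("stable-segment selection avoids noisy patches and movement", {
  set.seed(8)
  on <- cumsum(runif(15000, 0.24, 0.26))
  ## make minutes 20-22 wildly irregular
  noisy <- on > 1200 & on < 1320
  on[noisy] <- on[noisy] + runif(sum(noisy), -0.08, 0.08)
  b <- make_breath_table(sort(on))
  seg <- select_stable_segment(b, c(1100, 1500), length_s = 120)
  expect_false(is.null(seg))
  expect_true(seg[1] >= 1320 || seg[2] <= 1200)
  ## fully uniform window -> earliest candidate
  seg2 <- select_stable_segment(make_breath_table(seq(0, 600, by = 0.25)),
                                c(0, 600), length_s = 120)
  expect_equal(seg2[1], 0)
  ## window fully inside movement -> labeled absence (NULL)
  mv <- movement_mask(0, 700)
  expect_null(select_stable_segment(b, c(0, 600), 120, movement = mv))
})
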