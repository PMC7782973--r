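test_that("REOG equals the mean of the six EOG channels minus Pz", {
  # constant EOG, zero Pz -> constant
  eog <- matrix(2, 100, 6)
  expect_equal(compute_reog(eog, numeric(100)), rep(2, 100))
  # EOG == Pz everywhere -> zero
  pz <- rnorm(100)
  expect_equal(compute_reog(matrix(pz, 100, 6), pz), rep(0, 100))
  # random vectors match the brute-force formula
  set.seed(4)
  eogr <- matrix(rnorm(600), 100, 6)
  pzr <- rnorm(100)
  expect_equal(compute_reog(eogr, pzr), rowMeans(eogr) - pzr)
  expect_error(compute_reog(eogr, pzr[1:50]), "length")
})

test_that("saccade detector handles degenerate input and merges close
           spikes", {
  expect_equal(nrow(detect_saccades(numeric(5000))), 0)
  # two spikes 10 ms apart merge into one saccade
  fs <- 500
  set.seed(6)
  x <- rnorm(20000, sd = 1)
  spike <- 60 * sin(2 * pi * seq(0, 0.015, by = 1 / fs) / 0.015)
  i1 <- 10000
  i2 <- i1 + round(0.010 * fs) + length(spike)
  x[i1:(i1 + length(spike) - 1)] <- x[i1:(i1 + length(spike) - 1)] + spike
  x[i2:(i2 + length(spike) - 1)] <- x[i2:(i2 + length(spike) - 1)] + spike
  ev <- detect_saccades(x, fs)
  near <- ev[abs(ev$onset - i1) < 200, ]
  expect_equal(nrow(near), 1)
})

test_that("saccade detection is invariant to a constant REOG offset", {
  s <- walk_session()
  cm <- channel_map()
  reog <- compute_reog(s$eeg[, cm$eog], s$eeg[, "Pz"])
  ev1 <- detect_saccades(reog)
  ev2 <- detect_saccades(reog + 250)
  expect_equal(ev1$onset, ev2$onset)
})

test_that("blink detector applies threshold, ratio rule and 100-ms merge", {
  fs <- 500
  n <- 30000
  thr <- 40
  above <- numeric(n)
  below <- numeric(n)
  # one injected 250-ms blink peaking at 2x threshold -> one event
  bw <- 80 * 0.5 * (1 - cos(2 * pi * seq(0, 0.25, by = 1 / fs) / 0.25))
  above[5000:(5000 + length(bw) - 1)] <- bw
  ev <- detect_blinks(above, below, thr, fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset[1] - 5000) / fs, 0.05)
  # a slow drift whose supra-threshold segment is nearly flat
  # (sd/mean < 0.2) is excluded by the ratio rule
  drift <- numeric(n)
  wide <- 6 * thr * 0.5 * (1 - cos(2 * pi * seq(0, 8, by = 1 / fs) / 8))
  drift[2000:(2000 + length(wide) - 1)] <- wide
  ev2 <- detect_blinks(drift, below, thr, fs)
  expect_equal(nrow(ev2), 0)
  # two threshold crossings 50 ms apart merge into one blink: tall bumps
  # whose supra-threshold segments end/start ~80 ms apart
  tall <- 160 * 0.5 * (1 - cos(2 * pi * seq(0, 0.25, by = 1 / fs) / 0.25))
  two <- numeric(n)
  two[8000:(8000 + length(tall) - 1)] <- tall
  g2 <- 8000 + length(tall) - 20     # 40 ms overlap keeps crossings close
  two[g2:(g2 + length(tall) - 1)] <- two[g2:(g2 + length(tall) - 1)] + tall
  evm <- detect_blinks(two, below, thr, fs)
  expect_equal(nrow(evm), 1)
  expect_error(detect_blinks(above, below, -1), "positive")
})

test_that("blink threshold surrogate sits between noise and blink peaks,
           is robust to blink amplitude, and rarely fires on pure noise", {
  cfg <- gt_config(seed = 17L)
  s <- generate_session(cfg, "light", "normal")
  thr <- estimate_blink_threshold(s$eeg[, "EOGLA"], s$eeg[, "EOGLB"])
  # same subject, same noise stream, no blinks: noise peak < threshold
  cfg0 <- cfg
  cfg0$blink_rate[] <- 0
  s0 <- generate_session(cfg0, "light", "normal")
  v0 <- fir_filter(s0$eeg[, "EOGLA"] - s0$eeg[, "EOGLB"], 500, 0.2, 10)
  expect_gt(thr, quantile(abs(v0), 0.999))
  expect_lt(thr, cfg$blink_amp * 1.6)        # below the blink peak
  # doubling blink amplitude moves the threshold by < 10%
  cfg2 <- cfg
  cfg2$blink_amp <- cfg$blink_amp * 2
  s2 <- generate_session(cfg2, "light", "normal")
  thr2 <- estimate_blink_threshold(s2$eeg[, "EOGLA"], s2$eeg[, "EOGLB"])
  expect_lt(abs(thr2 - thr) / thr, 0.10)
  # pure-noise sessions: <= 1 false blink per minute at that threshold
  ev0 <- detect_blinks(s0$eeg[, "EOGLA"], s0$eeg[, "EOGLB"], thr)
  expect_lte(nrow(ev0) / (s0$duration / 60), 1)
  expect_error(estimate_blink_threshold(numeric(1000), numeric(1000)),
               "flat")
})

test_that("saccadic spike potential averaging recovers the template and
           noise shrinks as 1/sqrt(n)", {
  fs <- 500
  spike <- 40 * sin(2 * pi * seq(0, 0.015, by = 1 / fs) / 0.015)
  n <- 60000
  onsets <- seq(2000, 58000, by = 700)
  clean <- numeric(n)
  for (o in onsets) clean[o:(o + length(spike) - 1)] <- spike
  events <- tibble::tibble(onset = onsets)
  ssp <- saccadic_spike_potential(clean, events, fs)
  # identical spikes: the average reproduces the (band-passed) spike shape
  bf <- signal::butter(3, c(20, 90) / 250, type = "pass")
  template <- signal::filtfilt(bf, clean)[onsets[3] + (-25:25)]
  expect_equal(ssp$average, template, tolerance = 1e-6)
  expect_gt(ssp$peak_to_trough, 0.8 * (max(template) - min(template)))
  # residual averaging noise ~ 1/sqrt(n): quadrupling events halves it
  set.seed(12)
  noisy <- clean + rnorm(n, sd = 8)
  resid_for <- function(k) {
    ev <- tibble::tibble(onset = onsets[seq_len(k)])
    avg <- saccadic_spike_potential(noisy, ev, fs)$average
    sd(avg - ssp$average)
  }
  r1 <- mean(vapply(1:8, function(i) {
    set.seed(i); noisy <<- clean + rnorm(n, sd = 8); resid_for(20)
  }, 0))
  r2 <- mean(vapply(1:8, function(i) {
    set.seed(i); noisy <<- clean + rnorm(n, sd = 8); resid_for(80)
  }, 0))
  expect_lt(abs(r1 / r2 - 2) / 2, 0.20)
  expect_error(saccadic_spike_potential(clean,
                                        tibble::tibble(onset = integer(0))),
               "no events")
})

test_that("pupil processing: means, interpolation and the >99% rule", {
  # constant, no missing
  p <- process_pupil(rep(3, 1200))
  expect_equal(p$session_mean, 3)
  expect_false(p$excluded)
  # linear ramp with a 50% contiguous gap: interpolation error <= 1% range
  ramp <- seq(2, 6, length.out = 2400)
  gappy <- ramp
  gappy[600:1800] <- 0
  pr <- process_pupil(gappy)
  expect_lt(max(abs(pr$clean - ramp)) / diff(range(ramp)), 0.01)
  expect_false(any(pupil_missing_mask(pr$clean)))
  # 99.5% missing -> exclusion signal, not a crash
  mostly <- rep(0, 2000)
  mostly[sample(2000, 10)] <- 5
  pe <- process_pupil(mostly)
  expect_true(pe$excluded)
  expect_true(is.na(pe$session_mean))
})

test_that("event rates recovered from default synthetic sessions track the
           injected rates", {
  cfg <- gt_config(seed = 23L)
  recovered <- injected <- c(saccade = 0, blink = 0)
  n_sess <- 4
  for (i in seq_len(n_sess)) {
    s <- generate_session(cfg, if (i %% 2) "light" else "dark", "slow",
                          subject = i)
    thr <- estimate_blink_threshold(s$eeg[, "EOGLA"], s$eeg[, "EOGLB"])
    ev <- detect_eye_events(s, thr)
    recovered <- recovered + c(sum(ev$kind == "saccade"),
                               sum(ev$kind == "blink"))
    injected <- injected + c(length(s$truth$saccade_times),
                             length(s$truth$blink_times))
  }
  expect_lt(abs(recovered[["saccade"]] / injected[["saccade"]] - 1), 0.10)
  expect_lt(abs(recovered[["blink"]] / injected[["blink"]] - 1), 0.10)
})
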