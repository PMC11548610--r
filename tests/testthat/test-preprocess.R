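test_that("zero-phase filtering passes DC exactly and kills stopband tones", {
  fs <- 120
  t <- (0:1199) / fs

  # DC gain 1
  y <- lowpass_filter(rep(3.7, 300), fs)
  expect_lt(max(abs(y - 3.7)), 1e-9)

  # 30 Hz tone: steady-state residual below 1e-3 (analytic double-pass
  # attenuation is 1/(1 + (30/10)^8) ~ 1.5e-4); edges excluded where the
  # reflection padding cannot represent a strongly attenuated tone
  y30 <- lowpass_filter(sin(2 * pi * 30 * t), fs)
  interior <- 61:1140
  expect_lt(max(abs(y30[interior])), 1e-3)

  # superposition: mixed tone equals the sum of individually filtered parts
  x2 <- sin(2 * pi * 2 * t)
  x30 <- sin(2 * pi * 30 * t)
  ymix <- lowpass_filter(x2 + x30, fs)
  expect_equal(ymix, lowpass_filter(x2, fs) + lowpass_filter(x30, fs),
               tolerance = 1e-9)
  expect_gt(stats::cor(ymix[interior], lowpass_filter(x2, fs)[interior]),
            0.999)

  # zero phase: peak of a passband tone not shifted
  y2 <- lowpass_filter(x2, fs)
  expect_equal(which.max(y2[1:60]), which.max(x2[1:60]))

  expect_error(lowpass_filter(rnorm(10), fs), class = "canegait_data_error")
  expect_error(lowpass_filter(rnorm(100), fs, cutoff_hz = 60),
               class = "canegait_config_error")
})

test_that("jerk norm is the scaled first difference with duplicated first sample", {
  fs <- 120
  n <- 50

  # constant acceleration -> zero jerk
  acc <- matrix(5, n, 3)
  expect_equal(jerk_norm(acc, fs), rep(0, n))

  # linear ramp slope s on one axis -> constant |s| (hand finite difference:
  # diff = s/fs per sample, times fs = s)
  s <- 2.5
  acc <- cbind(s * (0:(n - 1)) / fs, rep(1, n), rep(-2, n))
  j <- jerk_norm(acc, fs)
  expect_equal(j, rep(s, n), tolerance = 1e-9)

  # unit step at index k -> single spike of magnitude fs at k
  k <- 20
  acc <- cbind(c(rep(0, k - 1), rep(1, n - k + 1)), rep(0, n), rep(0, n))
  j <- jerk_norm(acc, fs)
  expect_equal(j[k], fs)
  expect_equal(sum(j > 0), 1)
  expect_length(j, n)
  expect_true(all(j >= 0))
})

test_that("contact detection finds injected spikes and rejects flat series", {
  fs <- 120
  jerk <- rep(0, 500)
  jerk[c(100, 230, 360)] <- 50
  det <- detect_cane_contacts(jerk, fs)
  expect_equal(as.integer(det), c(100, 230, 360))

  # same spikes plus Gaussian noise: recovered within +-2 samples
  set.seed(42)
  jn <- abs(jerk + rnorm(500, sd = 1))
  det <- detect_cane_contacts(jn, fs)
  expect_length(det, 3)
  expect_true(all(abs(det - c(100, 230, 360)) <= 2))

  expect_error(detect_cane_contacts(rep(0, 500), fs),
               class = "canegait_no_contact_error")

  # refractory period: twin spikes closer than min separation yield one event
  jerk <- rep(0, 500)
  jerk[c(100, 110)] <- c(50, 40)
  det <- detect_cane_contacts(jerk, fs, min_separation_s = 0.5)
  expect_equal(as.integer(det), 100)
})

test_that("window extraction re-indexes contacts and excludes short trials", {
  fs <- 120
  n <- 600
  rec <- imu_recording("T", "S", fs, matrix(rnorm(n * 3), n, 3),
                       matrix(rnorm(n * 3), n, 3))

  win <- extract_analysis_window(rec, contacts = c(41L, 171L), window_len = 512)
  expect_equal(nrow(win$recording$acc), 512)
  # covers original samples 41..552
  expect_equal(win$recording$acc[1, 1], rec$acc[41, 1])
  expect_equal(win$recording$acc[512, 1], rec$acc[552, 1])

  expect_error(extract_analysis_window(rec, contacts = 201L, window_len = 512),
               class = "canegait_short_trial_error")

  # oracle: subtract the offset and drop contacts outside the window
  win <- extract_analysis_window(rec, c(41L, 171L, 301L, 431L, 561L), 512)
  expect_equal(win$contacts, c(1L, 131L, 261L, 391L))
})

test_that("cycle segmentation yields half-open cycles whose durations reconcile", {
  fs <- 120
  cy <- segment_cycles(c(1L, 131L, 261L), fs)
  expect_equal(nrow(cy), 2)
  expect_equal(cy$duration_s, rep(130 / 120, 2))

  expect_error(segment_cycles(1L, fs), class = "canegait_too_few_cycles_error")

  cy <- segment_cycles(c(1L, 121L, 251L, 381L), fs)
  expect_equal(mean(cy$duration_s), (120 + 130 + 130) / 3 / 120)
  # durations sum exactly to (last - first)/fs
  expect_equal(sum(cy$duration_s), (381 - 1) / fs)
  expect_true(all(cy$duration_s > 0))
})

test_that("detected contacts on simulated trials track the true impact onsets", {
  prof <- default_group_profile()
  # noiseless: every detection is a true contact (no spurious peaks)
  p <- prof$robust
  p$noise_sd_acc <- 0
  p$noise_sd_gyro <- 0
  tr <- simulate_trial(p, seed = 11, true_features = FALSE)
  pt <- process_trial(tr$recording)
  expect_equal(length(pt$contacts), length(tr$true_contacts))
  expect_true(all(abs(pt$contacts - tr$true_contacts) <= 3))
})
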