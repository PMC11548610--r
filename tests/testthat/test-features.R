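test_that("segment statistics match closed forms", {
  expect_equal(cycle_rms(c(3, -3, 3, -3)), 3)
  expect_equal(cycle_rms(c(1, 2, 3, 4)), sqrt(30 / 4))
  # sinusoid amplitude A over whole periods -> A/sqrt(2)
  A <- 2.7
  x <- A * sin(2 * pi * (0:479) / 120)  # 4 whole periods
  expect_equal(cycle_rms(x), A / sqrt(2), tolerance = 0.01)
  expect_error(cycle_rms(numeric(0)), class = "canegait_data_error")

  expect_equal(cycle_peak_angular_velocity(c(-5, 2, 4)), 5)
  expect_equal(cycle_peak_angular_velocity(rep(0, 10)), 0)
  expect_error(cycle_peak_angular_velocity(numeric(0)),
               class = "canegait_data_error")

  expect_equal(average_over_cycles(c(2, 4)), 3)
  expect_equal(average_over_cycles(7), 7)
  expect_error(average_over_cycles(numeric(0)), class = "canegait_data_error")
})

test_that("the windowed power spectrum obeys Parseval and leakage symmetry", {
  fs <- 120
  L <- 512

  ps <- power_spectrum(rep(0, L), fs)
  expect_true(all(ps$power == 0))
  expect_length(ps$power, L / 2 + 1)
  expect_equal(ps$freq_hz[2] - ps$freq_hz[1], fs / L)
  expect_error(power_spectrum(rep(0, 100), fs), class = "canegait_data_error")

  # on-bin tone at bin 9: periodic-Hamming leakage is symmetric about it
  f9 <- 9 * fs / L
  x <- sin(2 * pi * f9 * (0:(L - 1)) / fs)
  ps <- power_spectrum(x, fs)
  i0 <- 10  # 1-based index of bin 9
  for (j in 1:2)
    expect_equal(ps$power[i0 - j], ps$power[i0 + j], tolerance = 1e-6)

  # Parseval: one-sided power sums to L * windowed time-domain energy
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(L)
    ps <- power_spectrum(x, fs)
    w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / L)
    expect_equal(sum(ps$power), L * sum((x * w)^2), tolerance = 1e-9)
  }
})

test_that("fast transform agrees with a direct DFT oracle", {
  set.seed(8)
  for (i in 1:3) {
    x <- rnorm(512)
    expect_equal(stats::fft(x), brute_dft(x), tolerance = 1e-9)
  }
})

test_that("mean power frequency is the band-limited spectral centroid", {
  fs <- 120
  L <- 512
  tt <- (0:(L - 1)) / fs
  f9 <- 9 * fs / L     # 2.109375 Hz
  f30 <- 30 * fs / L   # 7.03125 Hz

  ps <- power_spectrum(sin(2 * pi * f9 * tt), fs)
  expect_equal(mean_power_frequency(ps), f9, tolerance = 1e-3)

  ps <- power_spectrum(sin(2 * pi * f9 * tt) + sin(2 * pi * f30 * tt), fs)
  expect_equal(mean_power_frequency(ps), (f9 + f30) / 2, tolerance = 5e-3)

  expect_error(mean_power_frequency(power_spectrum(rep(0, L), fs)),
               class = "canegait_zero_power_error")

  # white noise: mean MPF approaches the flat-spectrum centroid, i.e. the
  # midpoint of the included bins (bins 3..42 at the defaults)
  bins <- (0:(L / 2)) * fs / L
  included <- bins[bins >= 0.5 & bins <= 10]
  flat_centroid <- mean(included)
  set.seed(31)
  mpfs <- replicate(200, mean_power_frequency(power_spectrum(rnorm(L), fs)))
  expect_equal(mean(mpfs), flat_centroid, tolerance = 0.1)
})

test_that("trial features are scale-equivariant and cycle-order invariant", {
  tr <- simulate_trial(gait_sim_params(), seed = 21)
  pt <- process_trial(tr$recording)

  # doubling the acceleration doubles RMS, leaves MPF (and gyro) unchanged
  rec2 <- tr$recording
  rec2$acc <- rec2$acc * 2
  pt2 <- process_trial(rec2)
  for (f in c("rms_vt", "rms_ap", "rms_ml"))
    expect_equal(pt2$features[[f]], 2 * pt$features[[f]], tolerance = 1e-6)
  for (f in c("mpf_vt", "mpf_ap", "mpf_ml", "pav_vt", "pav_ap", "pav_ml"))
    expect_equal(pt2$features[[f]], pt$features[[f]], tolerance = 1e-6)

  # MPF stays inside the configured band by construction
  for (f in c("mpf_vt", "mpf_ap", "mpf_ml")) {
    expect_gte(pt$features[[f]], 0.5)
    expect_lte(pt$features[[f]], 10)
  }

  # shuffling cycle order leaves the averaged features unchanged
  win <- extract_analysis_window(
    filter_recording(tr$recording), pt$contacts)
  cy <- segment_cycles(win$contacts, 120)
  f1 <- extract_trial_features(win$recording, cy)
  f2 <- extract_trial_features(win$recording, cy[rev(seq_len(nrow(cy))), ])
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("noiseless single-harmonic trials recover the generator closed forms", {
  w <- matrix(0, 4, 3, dimnames = list(NULL, c("vt", "ap", "ml")))
  w[1, ] <- 1
  p <- gait_sim_params(a_vt = 2, a_ap = 1.5, a_ml = 0.8,
                       harmonic_weights = w, phase_jitter_sd = 0,
                       impact_amp = 0, noise_sd_acc = 0, noise_sd_gyro = 0,
                       stride_time_sd_s = 0)
  tr <- simulate_trial(p, seed = 3)
  f <- tr$true_features
  # pure sinusoid per axis: RMS = a/sqrt(2) within 2%
  expect_equal(f$rms_vt, 2 / sqrt(2), tolerance = 0.02)
  expect_equal(f$rms_ap, 1.5 / sqrt(2), tolerance = 0.02)
  expect_equal(f$rms_ml, 0.8 / sqrt(2), tolerance = 0.02)
  # MPF at the stride frequency within one FFT bin
  f_stride <- 1 / p$stride_time_mean_s
  bin <- 120 / 512
  for (nm in c("mpf_vt", "mpf_ap", "mpf_ml"))
    expect_lt(abs(f[[nm]] - f_stride), bin)
  # peak angular velocity equals the swing amplitude
  expect_equal(f$pav_ap, p$g_ap, tolerance = 0.01)
})

test_that("cohort feature extraction logs exclusions and reconciles counts", {
  co <- simulate_cohort(n_frail = 2, n_robust = 3, seed = 5,
                        trials_per_subject = 2)
  cfg <- default_run_config()
  fx <- extract_cohort_features(co, cfg)
  expect_equal(nrow(fx$features) + nrow(fx$exclusions), nrow(co$manifest))
  expect_equal(nrow(fx$exclusions), 0)

  # an oversized window makes every trial a short-trial exclusion
  cfg$window_len_samples <- 4096L
  fx2 <- extract_cohort_features(co, cfg)
  expect_equal(nrow(fx2$exclusions), nrow(co$manifest))
  expect_true(all(fx2$exclusions$reason == "canegait_short_trial_error"))
})
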