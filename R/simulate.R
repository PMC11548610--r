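default_harmonic_weights <- function() {
  cbind(vt = c(0.55, 0.25, 0.12, 0.08),
        ap = c(0.60, 0.22, 0.11, 0.07),
        ml = c(0.50, 0.28, 0.14, 0.08))
}

default_harmonic_phases <- function() {
  # fixed gait-pattern constants (radians): the waveform is phase-locked to
  # the cane contact (stride phase 0), as in real two-point gait
  cbind(vt = c(2.0, 0.8, 4.1, 2.9),
        ap = c(1.2, 3.5, 0.4, 5.0),
        ml = c(0.6, 2.2, 3.9, 1.4))
}

#' Parameters of the synthetic cane-gait signal model
#'
#' The model emulates two-point cane gait as seen by a cane-mounted IMU:
#' a quasi-periodic stride oscillation (four harmonics of the stride
#' frequency with per-axis amplitudes and weights), a sharp exponentially
#' decaying impact transient on the acceleration channels at every cane
#' ground contact, a smooth raised-cosine angular-velocity swing per
#' stride, a constant gravity offset on the vertical accelerometer axis,
#' and additive white Gaussian sensor noise. Stride periods are drawn
#' i.i.d. from a normal distribution truncated at three standard
#' deviations.
#'
#' @param stride_time_mean_s,stride_time_sd_s stride (cane-contact to
#'   cane-contact) period mean and sd, seconds.
#' @param a_vt,a_ap,a_ml oscillation amplitude per axis, m/s^2.
#' @param harmonic_weights 4 x 3 matrix (columns vt, ap, ml), each column
#'   summing to 1; controls the spectral shape of each axis.
#' @param harmonic_phases 4 x 3 matrix of fixed harmonic phases (radians)
#'   relative to the cane contact; the oscillation is phase-locked to the
#'   gait cycle.
#' @param phase_jitter_sd per-trial Gaussian jitter (radians) added to the
#'   harmonic phases.
#' @param impact_amp impact transient amplitude, m/s^2.
#' @param impact_tau_s impact decay time constant, seconds (much shorter
#'   than a stride).
#' @param impact_axis_weights relative impact amplitude on vt/ap/ml.
#' @param g_vt,g_ap,g_ml peak angular-velocity swing per axis, deg/s.
#' @param noise_sd_acc,noise_sd_gyro white-noise sd, m/s^2 and deg/s.
#' @param gravity_offset_mps2 constant offset added to the vertical
#'   acceleration channel.
#' @param n_strides number of strides simulated (>= 3).
#' @param sample_rate_hz sampling rate.
#' @return object of class `gait_sim_params`.
#' @export
gait_sim_params <- function(stride_time_mean_s = 1.10, stride_time_sd_s = 0.05,
                            a_vt = 2.0, a_ap = 1.5, a_ml = 0.8,
                            harmonic_weights = default_harmonic_weights(),
                            harmonic_phases = default_harmonic_phases(),
                            phase_jitter_sd = 0.2,
                            impact_amp = 8, impact_tau_s = 0.05,
                            impact_axis_weights = c(vt = 1, ap = 0.4, ml = 0.25),
                            g_vt = 30, g_ap = 60, g_ml = 25,
                            noise_sd_acc = 0.05, noise_sd_gyro = 0.5,
                            gravity_offset_mps2 = 9.80665,
                            n_strides = 8L, sample_rate_hz = 120) {
  p <- list(stride_time_mean_s = stride_time_mean_s,
            stride_time_sd_s = stride_time_sd_s,
            a_vt = a_vt, a_ap = a_ap, a_ml = a_ml,
            harmonic_weights = as.matrix(harmonic_weights),
            harmonic_phases = as.matrix(harmonic_phases),
            phase_jitter_sd = phase_jitter_sd,
            impact_amp = impact_amp, impact_tau_s = impact_tau_s,
            impact_axis_weights = impact_axis_weights,
            g_vt = g_vt, g_ap = g_ap, g_ml = g_ml,
            noise_sd_acc = noise_sd_acc, noise_sd_gyro = noise_sd_gyro,
            gravity_offset_mps2 = gravity_offset_mps2,
            n_strides = as.integer(n_strides),
            sample_rate_hz = sample_rate_hz)
  class(p) <- "gait_sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  amps <- c(p$a_vt, p$a_ap, p$a_ml, p$impact_amp, p$g_vt, p$g_ap, p$g_ml,
            p$noise_sd_acc, p$noise_sd_gyro)
  if (any(amps < 0))
    abort_canegait("all amplitudes must be non-negative",
                   "canegait_config_error")
  if (p$stride_time_mean_s <= 0 || p$stride_time_sd_s < 0)
    abort_canegait("stride time mean must be positive and sd non-negative",
                   "canegait_config_error")
  w <- p$harmonic_weights
  if (!is.matrix(w) || ncol(w) != 3 ||
      any(abs(colSums(w) - 1) > 1e-8) || any(w < 0))
    abort_canegait("harmonic_weights must be a non-negative 4 x 3 matrix with columns summing to 1",
                   "canegait_config_error")
  if (p$n_strides < 3)
    abort_canegait("n_strides must be >= 3", "canegait_config_error")
  if (p$impact_tau_s <= 0 || p$impact_tau_s > p$stride_time_mean_s / 5)
    abort_canegait("impact_tau_s must be positive and much shorter than a stride",
                   "canegait_config_error")
  invisible(p)
}

scale_sim_params <- function(p, amp_mult = 1, stride_mult = 1) {
  for (nm in c("a_vt", "a_ap", "a_ml", "g_vt", "g_ap", "g_ml", "impact_amp"))
    p[[nm]] <- p[[nm]] * amp_mult
  p$stride_time_mean_s <- p$stride_time_mean_s * stride_mult
  p
}

#' Group presets for the synthetic cohort
#'
#' Two calibrated `gait_sim_params` presets. Relative to the robust preset
#' the frail preset has smaller vertical and anteroposterior oscillation
#' (and proportionally softer impacts), a smaller anteroposterior swing
#' velocity, and vertical harmonic weights shifted toward the higher
#' harmonics, which raises the vertical mean power frequency. The
#' multipliers are derived analytically from the rank-biserial separation
#' each target effect size implies under the default between-subject
#' (sd 0.10) and between-trial (sd 0.05) log-normal variability; see the
#' package vignette.
#'
#' @return object of class `group_profile`: list with elements `robust`
#'   and `frail`.
#' @export
default_group_profile <- function() {
  robust <- gait_sim_params()
  frail_w <- default_harmonic_weights()
  frail_w[, "vt"] <- c(0.45, 0.28, 0.17, 0.10)
  frail <- gait_sim_params(
    a_vt = 2.0 * 0.9546, a_ap = 1.5 * 0.9015, a_ml = 0.8,
    impact_amp = 8 * 0.9546,
    g_vt = 30 * 0.9697, g_ap = 60 * 0.9233, g_ml = 25,
    harmonic_weights = frail_w)
  structure(list(robust = robust, frail = frail), class = "group_profile")
}

#' Simulate one cane-IMU walking trial
#'
#' Deterministic for a fixed seed. Returns the noisy recording together
#' with the ground truth: the impact-onset sample indices (one per cane
#' contact, `n_strides + 1` in total), the drawn stride periods, and the
#' feature vector the analysis pipeline recovers from the noiseless signal
#' using the true contacts.
#'
#' @param params a [gait_sim_params()].
#' @param seed integer seed.
#' @param trial_id,subject_id identifiers stored in the recording.
#' @param true_features compute the reference features from the noiseless
#'   signal (costs one extra pipeline pass).
#' @return object of class `simulated_trial`.
#' @export
simulate_trial <- function(params, seed, trial_id = "T1", subject_id = "S1",
                           true_features = TRUE) {
  validate_sim_params(params)
  with_seed(seed, {
    fs <- params$sample_rate_hz
    ns <- params$n_strides

    # stride periods: normal truncated at +/- 3 sd via the quantile transform
    u <- stats::runif(ns, stats::pnorm(-3), stats::pnorm(3))
    d <- params$stride_time_mean_s + params$stride_time_sd_s * stats::qnorm(u)

    t_contact <- 0.5 + c(0, cumsum(d))
    t_end <- max(t_contact) + 0.6
    n <- ceiling(t_end * fs)
    t <- (seq_len(n) - 1) / fs

    # stride phase: advances by 2*pi per stride, piecewise linear between
    # contacts, extrapolated with the first/last period outside them
    knots_t <- c(t_contact[1] - d[1], t_contact, t_contact[ns + 1] + d[ns])
    knots_ph <- 2 * pi * (-1:(ns + 1))
    phase <- stats::approx(knots_t, knots_ph, xout = t)$y

    amps <- c(vt = params$a_vt, ap = params$a_ap, ml = params$a_ml)
    gs <- c(vt = params$g_vt, ap = params$g_ap, ml = params$g_ml)
    phi <- params$harmonic_phases +
      matrix(stats::rnorm(12, 0, params$phase_jitter_sd), nrow = 4)

    acc <- matrix(0, n, 3, dimnames = list(NULL, axis_names()))
    gyro <- matrix(0, n, 3, dimnames = list(NULL, axis_names()))
    for (ax in 1:3) {
      s <- 0
      for (k in 1:4)
        s <- s + params$harmonic_weights[k, ax] * amps[ax] *
          sin(k * phase + phi[k, ax])
      acc[, ax] <- s
      gyro[, ax] <- gs[ax] * 0.5 * (1 - cos(phase))
    }

    # impact transient: exponential pulse starting exactly on a sample
    contact_idx <- round(t_contact * fs) + 1L
    pulse_len <- ceiling(10 * params$impact_tau_s * fs)
    pulse <- exp(-(0:(pulse_len - 1)) / (params$impact_tau_s * fs))
    for (ci in contact_idx) {
      span <- ci:min(ci + pulse_len - 1L, n)
      for (ax in 1:3)
        acc[span, ax] <- acc[span, ax] +
          params$impact_amp * params$impact_axis_weights[ax] *
          pulse[seq_along(span)]
    }
    acc[, "vt"] <- acc[, "vt"] + params$gravity_offset_mps2

    noiseless <- imu_recording(trial_id, subject_id, fs, acc, gyro)
    acc_n <- acc + matrix(stats::rnorm(n * 3, sd = params$noise_sd_acc), n, 3)
    gyro_n <- gyro + matrix(stats::rnorm(n * 3, sd = params$noise_sd_gyro), n, 3)
    rec <- imu_recording(trial_id, subject_id, fs, acc_n, gyro_n)

    tf <- NULL
    if (true_features) {
      frec <- filter_recording(noiseless)
      win <- extract_analysis_window(frec, contact_idx)
      cycles <- segment_cycles(win$contacts, fs)
      tf <- extract_trial_features(win$recording, cycles)
    }

    structure(
      list(recording = rec, noiseless = noiseless,
           true_contacts = contact_idx, true_stride_times_s = d,
           true_features = tf, params = params, seed = seed),
      class = "simulated_trial")
  })
}

allocate_trials <- function(n_subjects, n_trials) {
  base <- n_trials %/% n_subjects
  extra <- n_trials %% n_subjects
  c(rep(base + 1L, extra), rep(base, n_subjects - extra))
}

#' Threshold five questionnaire items into a frailty label
#'
#' Applies the screening rule for the five exercise-related questionnaire
#' items: a subject with three or more negative answers is labelled frail.
#'
#' @param responses vector of five binary negative-answer indicators.
#' @return `"frail"` or `"robust"`.
#' @export
kcl_label <- function(responses) {
  if (length(responses) != 5 || !all(responses %in% c(0, 1)))
    abort_canegait("responses must be five binary items",
                   "canegait_data_error")
  if (sum(responses) >= 3) "frail" else "robust"
}

#' Simulate a two-group cane-gait cohort
#'
#' Generates trials for `n_frail` frail and `n_robust` robust subjects.
#' Subject-level log-normal random effects multiply the group preset's
#' amplitudes (and, separately, the mean stride time), so trials within a
#' subject are correlated; an additional trial-level multiplier captures
#' within-subject variability. Each subject also answers the five
#' exercise-related questionnaire items with a group-dependent
#' negative-answer probability, and the screening rule of [kcl_label()] is
#' applied. By default the manifest carries the generating group as the
#' frailty label (so the cohort composition is exact); `label_source =
#' "kcl"` uses the questionnaire-derived label instead.
#'
#' With the defaults (14 frail / 31 robust subjects) the trial allocation
#' reproduces a 37 / 94 trial composition.
#'
#' @param n_frail,n_robust number of subjects per group.
#' @param trials_per_subject `NULL` for the default allocation, a single
#'   count, or a list with elements `frail` and `robust` giving per-subject
#'   counts.
#' @param profile a [default_group_profile()].
#' @param seed integer seed; the cohort is a pure function of it.
#' @param subject_amp_sd,trial_amp_sd log-normal sd of the subject- and
#'   trial-level amplitude multipliers.
#' @param subject_stride_sd log-normal sd of the subject-level stride-time
#'   multiplier.
#' @param kcl_neg_prob named vector: per-item negative-answer probability
#'   for each group.
#' @param label_source `"group"` or `"kcl"`.
#' @param true_features forwarded to [simulate_trial()]; off by default to
#'   halve cohort simulation cost.
#' @return object of class `gait_cohort`: list with `manifest`, `trials`
#'   (named by trial_id), and `kcl` (per-subject responses and label).
#' @export
simulate_cohort <- function(n_frail = 14, n_robust = 31,
                            trials_per_subject = NULL,
                            profile = default_group_profile(), seed = 1,
                            subject_amp_sd = 0.10, trial_amp_sd = 0.05,
                            subject_stride_sd = 0.06,
                            kcl_neg_prob = c(frail = 0.85, robust = 0.15),
                            label_source = c("group", "kcl"),
                            true_features = FALSE) {
  label_source <- match.arg(label_source)
  stopifnot(n_frail >= 0, n_robust >= 0, n_frail + n_robust >= 1)

  alloc <- list(
    frail = if (n_frail > 0) allocate_trials(n_frail, round(n_frail * 37 / 14))
            else integer(0),
    robust = if (n_robust > 0) allocate_trials(n_robust, round(n_robust * 94 / 31))
             else integer(0))
  if (!is.null(trials_per_subject)) {
    if (is.list(trials_per_subject)) alloc <- trials_per_subject
    else alloc <- list(frail = rep(trials_per_subject, n_frail),
                       robust = rep(trials_per_subject, n_robust))
  }

  with_seed(seed, {
    groups <- c(rep("frail", n_frail), rep("robust", n_robust))
    n_sub <- length(groups)
    subject_id <- sprintf("S%02d", seq_len(n_sub))
    amp_sub <- exp(stats::rnorm(n_sub, 0, subject_amp_sd))
    stride_sub <- exp(stats::rnorm(n_sub, 0, subject_stride_sd))

    kcl <- t(vapply(groups, function(g)
      stats::rbinom(5, 1, kcl_neg_prob[[g]]), numeric(5)))
    dimnames(kcl) <- list(NULL, paste0("item", 1:5))
    kcl_lab <- apply(kcl, 1, kcl_label)

    rows <- list()
    trials <- list()
    k <- 0L
    for (i in seq_len(n_sub)) {
      g <- groups[i]
      nt <- c(alloc$frail, alloc$robust)[i]
      for (j in seq_len(nt)) {
        k <- k + 1L
        trial_id <- sprintf("%s_T%d", subject_id[i], j)
        amp_tr <- exp(stats::rnorm(1, 0, trial_amp_sd))
        p <- scale_sim_params(profile[[g]],
                              amp_mult = amp_sub[i] * amp_tr,
                              stride_mult = stride_sub[i])
        tr_seed <- sample.int(2147483646L, 1)
        trials[[trial_id]] <- simulate_trial(
          p, seed = tr_seed, trial_id = trial_id,
          subject_id = subject_id[i], true_features = true_features)
        rows[[k]] <- data.frame(
          subject_id = subject_id[i], trial_id = trial_id,
          trial_file = paste0(trial_id, ".csv"),
          frail_label = if (label_source == "group") g else kcl_lab[i],
          group = g)
      }
    }
    manifest <- do.call(rbind, rows)
    structure(
      list(manifest = manifest, trials = trials,
           kcl = data.frame(subject_id = subject_id, group = groups,
                            kcl, n_negative = rowSums(kcl),
                            kcl_label = kcl_lab),
           seed = seed),
      class = "gait_cohort")
  })
}

#' Write a simulated cohort to disk
#'
#' Emits one trial CSV per trial, the cohort manifest, and a ground-truth
#' JSON with the true contact indices and stride times per trial.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tid in names(cohort$trials))
    write_trial_csv(cohort$trials[[tid]]$recording,
                    file.path(dir, paste0(tid, ".csv")))
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  truth <- lapply(cohort$trials, function(tr)
    list(true_contacts = tr$true_contacts,
         true_stride_times_s = tr$true_stride_times_s))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
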