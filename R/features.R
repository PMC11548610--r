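#' Root mean square of a signal segment
#'
#' @param x non-empty numeric segment (mean-removed filtered acceleration
#'   when used for the trial features).
#' @return `sqrt(mean(x^2))`.
#' @export
cycle_rms <- function(x) {
  if (!length(x))
    abort_canegait("empty segment", "canegait_data_error")
  sqrt(mean(x^2))
}

#' Peak (unsigned) angular velocity of a segment
#'
#' @param x non-empty numeric segment of one angular-velocity axis.
#' @return `max(abs(x))`.
#' @export
cycle_peak_angular_velocity <- function(x) {
  if (!length(x))
    abort_canegait("empty segment", "canegait_data_error")
  max(abs(x))
}

#' Average per-cycle values
#'
#' @param values one value per gait cycle.
#' @return arithmetic mean.
#' @export
average_over_cycles <- function(values) {
  if (!length(values))
    abort_canegait("no per-cycle values to average", "canegait_data_error")
  mean(values)
}

hamming_window <- function(n) {
  # periodic form: w[k] = 0.54 - 0.46 cos(2*pi*k/n), k = 0..n-1
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / n)
}

#' One-sided power spectrum with a periodic Hamming window
#'
#' Multiplies the (mean-removed) signal by a periodic Hamming window,
#' applies the FFT, and returns the one-sided power `|X|^2` with interior
#' bins doubled. At the 512-sample / 120 Hz defaults the bin spacing is
#' 0.234375 Hz.
#'
#' @param x numeric signal whose length must equal `window_len` (a power of
#'   two, even).
#' @param sample_rate_hz sampling rate.
#' @param window_len expected window length (default 512).
#' @return object of class `power_spectrum`: list with `freq_hz` (bin
#'   centres from 0) and `power`.
#' @export
power_spectrum <- function(x, sample_rate_hz, window_len = 512) {
  n <- length(x)
  if (n != window_len)
    abort_canegait(sprintf("signal length %d != window length %d", n,
                           window_len), "canegait_data_error")
  if (n %% 2 != 0)
    abort_canegait("window length must be even", "canegait_config_error")
  w <- hamming_window(n)
  X <- stats::fft(x * w)
  half <- n / 2 + 1
  p <- Mod(X[seq_len(half)])^2
  p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  structure(
    list(freq_hz = (seq_len(half) - 1) * sample_rate_hz / n,
         power = p, sample_rate_hz = sample_rate_hz, n = n),
    class = "power_spectrum")
}

#' Band-limited mean power frequency (spectral centroid)
#'
#' Power-weighted mean frequency over the bins whose centres fall inside
#' the band (both endpoints inclusive); at the defaults the band 0.5-10 Hz
#' spans bins 3 to 42 of the 512-point transform.
#'
#' @param spec a [power_spectrum()].
#' @param band_hz numeric `c(lower, upper)` in Hz.
#' @return mean power frequency in Hz.
#' @export
mean_power_frequency <- function(spec, band_hz = c(0.5, 10)) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (band_hz[1] >= band_hz[2])
    abort_canegait("band lower bound must be below upper bound",
                   "canegait_config_error")
  sel <- spec$freq_hz >= band_hz[1] & spec$freq_hz <= band_hz[2]
  p <- spec$power[sel]
  if (!any(sel) || sum(p) <= 0)
    abort_canegait("zero in-band power: mean power frequency undefined",
                   "canegait_zero_power_error")
  sum(spec$freq_hz[sel] * p) / sum(p)
}

#' Extract the ten trial-level features from a windowed recording
#'
#' RMS of acceleration and peak angular velocity are computed per gait
#' cycle per axis and averaged across cycles; the mean power frequency is
#' computed once per acceleration axis on the full analysis window; stride
#' time is the mean cycle duration. The per-axis window mean is removed
#' from the acceleration before both RMS and FFT (`demean = TRUE`), so the
#' gravity component does not dominate the vertical channel.
#'
#' @param wrec the windowed recording from [extract_analysis_window()].
#' @param cycles cycle table from [segment_cycles()].
#' @param mpf_band_hz band for [mean_power_frequency()].
#' @param demean remove the per-axis window mean from the acceleration.
#' @return one-row data frame with the features of [canegait_features()]
#'   plus `n_cycles`.
#' @export
extract_trial_features <- function(wrec, cycles, mpf_band_hz = c(0.5, 10),
                                   demean = TRUE) {
  if (nrow(cycles) < 1)
    abort_canegait("need at least one complete gait cycle",
                   "canegait_too_few_cycles_error")
  acc <- wrec$acc
  if (demean) acc <- sweep(acc, 2, colMeans(acc))
  gyro <- wrec$gyro
  fs <- wrec$sample_rate_hz
  n <- nrow(acc)

  seg <- function(x, i) x[cycles$start[i]:(cycles$end[i] - 1)]
  rms <- vapply(seq_len(3), function(ax) {
    average_over_cycles(vapply(seq_len(nrow(cycles)),
                               function(i) cycle_rms(seg(acc[, ax], i)),
                               numeric(1)))
  }, numeric(1))
  pav <- vapply(seq_len(3), function(ax) {
    average_over_cycles(vapply(seq_len(nrow(cycles)),
                               function(i) cycle_peak_angular_velocity(seg(gyro[, ax], i)),
                               numeric(1)))
  }, numeric(1))
  mpf <- vapply(seq_len(3), function(ax) {
    mean_power_frequency(power_spectrum(acc[, ax], fs, window_len = n),
                         band_hz = mpf_band_hz)
  }, numeric(1))

  out <- data.frame(
    rms_vt = rms[1], rms_ap = rms[2], rms_ml = rms[3],
    mpf_vt = mpf[1], mpf_ap = mpf[2], mpf_ml = mpf[3],
    pav_vt = pav[1], pav_ap = pav[2], pav_ml = pav[3],
    stride_time_s = mean(cycles$duration_s),
    n_cycles = nrow(cycles))
  out
}

#' Run the per-trial analysis chain
#'
#' Filter, jerk norm, contact detection, window extraction, cycle
#' segmentation and feature extraction for one recording. Unusable trials
#' raise typed conditions (`canegait_no_contact_error`,
#' `canegait_short_trial_error`, `canegait_too_few_cycles_error`) which the
#' cohort-level wrapper converts into exclusions.
#'
#' @param rec an [imu_recording()].
#' @param config a [default_run_config()].
#' @return list with `features` (one-row data frame), `contacts` (original
#'   indices), `window_contacts`, `cycles` and `window_offset`.
#' @export
process_trial <- function(rec, config = default_run_config()) {
  frec <- filter_recording(rec, cutoff_hz = config$filter$cutoff_hz,
                           order = config$filter$order)
  jerk <- jerk_norm(frec$acc, frec$sample_rate_hz)
  contacts <- detect_cane_contacts(
    jerk, frec$sample_rate_hz,
    threshold_k = config$contacts$threshold_k,
    min_separation_s = config$contacts$min_separation_s)
  win <- extract_analysis_window(frec, contacts,
                                 window_len = config$window_len_samples)
  cycles <- segment_cycles(win$contacts, frec$sample_rate_hz)
  feats <- extract_trial_features(win$recording, cycles,
                                  mpf_band_hz = config$mpf_band_hz,
                                  demean = config$demean_window)
  list(features = feats, contacts = as.integer(contacts),
       window_contacts = win$contacts, cycles = cycles,
       window_offset = win$offset)
}

#' Build the cohort feature table
#'
#' Runs [process_trial()] over every trial of a simulated cohort (or a
#' manifest plus a directory of trial CSVs) and assembles the feature
#' table. Trials that fail with a typed condition are excluded and logged
#' with their reason rather than aborting the run.
#'
#' @param cohort a [simulate_cohort()] result, or `NULL` when reading from
#'   disk.
#' @param config run configuration.
#' @param manifest,dir alternative input: a manifest data frame and the
#'   directory holding its `trial_file`s.
#' @return list with `features` (data frame, one row per analysed trial)
#'   and `exclusions` (data frame of trial_id / reason).
#' @export
extract_cohort_features <- function(cohort = NULL,
                                    config = default_run_config(),
                                    manifest = NULL, dir = NULL) {
  if (!is.null(cohort)) {
    manifest <- cohort$manifest
    get_rec <- function(i) cohort$trials[[manifest$trial_id[i]]]$recording
  } else {
    stopifnot(!is.null(manifest), !is.null(dir))
    validate_manifest(manifest)
    get_rec <- function(i) read_trial_csv(
      file.path(dir, manifest$trial_file[i]),
      trial_id = manifest$trial_id[i],
      subject_id = manifest$subject_id[i])
  }
  rows <- vector("list", nrow(manifest))
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(process_trial(get_rec(i), config),
                    canegait_error = function(e) e)
    if (inherits(res, "canegait_error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        trial_id = manifest$trial_id[i],
        reason = class(res)[1])
    } else {
      rows[[i]] <- cbind(
        data.frame(trial_id = manifest$trial_id[i],
                   subject_id = manifest$subject_id[i],
                   frail_label = manifest$frail_label[i]),
        res$features)
    }
  }
  list(features = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(trial_id = character(0), reason = character(0)))
}
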