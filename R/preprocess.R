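#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase), so detected event times are not shifted relative to the raw
#' signal. Edge transients are controlled by odd-reflection padding of
#' length `3 * order` with steady-state initialisation, so a constant input
#' is returned unchanged to machine precision. The effective amplitude
#' response of the double pass is the squared single-pass response,
#' 1 / (1 + (f/fc)^(2*order)).
#'
#' @param x numeric vector.
#' @param sample_rate_hz sampling rate in Hz.
#' @param cutoff_hz cutoff frequency (default 10 Hz).
#' @param order filter order of each pass (default 4).
#' @return filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, sample_rate_hz, cutoff_hz = 10, order = 4) {
  nfact <- 3L * order
  if (length(x) <= nfact)
    abort_canegait(sprintf("input too short to filter (need > %d samples)",
                           nfact), "canegait_data_error")
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2)
    abort_canegait("cutoff must lie in (0, Nyquist)", "canegait_config_error")
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  b <- bf$b
  a <- bf$a
  dc <- sum(b) / sum(a)
  nx <- length(x)
  pre <- 2 * x[1] - x[(nfact + 1):2]
  post <- 2 * x[nx] - x[(nx - 1):(nx - nfact)]
  xx <- c(pre, x, post)
  one_pass <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1], length(b) - 1),
                              init.y = rep(v[1] * dc, length(a) - 1)))
  }
  y <- rev(one_pass(rev(one_pass(xx))))
  y[(nfact + 1):(nfact + nx)]
}

#' Low-pass filter all six channels of a recording
#'
#' @param rec an [imu_recording()].
#' @param cutoff_hz,order filter parameters, see [lowpass_filter()].
#' @return a `filtered_recording` (an `imu_recording` carrying filter
#'   provenance in its `filter` field).
#' @export
filter_recording <- function(rec, cutoff_hz = 10, order = 4) {
  stopifnot(inherits(rec, "imu_recording"))
  fs <- rec$sample_rate_hz
  out <- rec
  out$acc <- apply(rec$acc, 2, lowpass_filter, sample_rate_hz = fs,
                   cutoff_hz = cutoff_hz, order = order)
  out$gyro <- apply(rec$gyro, 2, lowpass_filter, sample_rate_hz = fs,
                    cutoff_hz = cutoff_hz, order = order)
  colnames(out$acc) <- colnames(out$gyro) <- axis_names()
  out$filter <- list(cutoff_hz = cutoff_hz, order = order,
                     phase = "zero (forward-backward)")
  class(out) <- c("filtered_recording", "imu_recording")
  out
}

#' Jerk norm of a tri-axial acceleration signal
#'
#' Per-axis first difference scaled by the sample rate (m/s^3), combined as
#' the Euclidean norm across axes. The first sample is duplicated so the
#' output has the same length as the input; spikes in this series mark cane
#' ground contacts. A first (not centred) difference is used deliberately to
#' keep impact spikes sharp.
#'
#' @param acc N x 3 acceleration matrix (ideally already low-pass filtered).
#' @param sample_rate_hz sampling rate.
#' @return non-negative numeric vector of length N.
#' @export
jerk_norm <- function(acc, sample_rate_hz) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2)
    abort_canegait("need at least 2 samples for the jerk norm",
                   "canegait_data_error")
  d <- diff(acc) * sample_rate_hz
  j <- sqrt(rowSums(d^2))
  c(j[1], j)
}

#' Detect cane ground contacts from the jerk norm
#'
#' Local maxima of the jerk series exceeding `mean + threshold_k * sd` are
#' accepted greedily in descending height, enforcing a minimum separation
#' (refractory period) of `min_separation_s`, and returned sorted in time.
#'
#' @param jerk jerk-norm vector from [jerk_norm()].
#' @param sample_rate_hz sampling rate.
#' @param threshold_k threshold in standard deviations above the mean.
#' @param min_separation_s minimum separation between contacts in seconds;
#'   0.5 s is a safe refractory period for stride times near one second.
#' @return strictly increasing integer sample indices (class
#'   `contact_events`).
#' @export
detect_cane_contacts <- function(jerk, sample_rate_hz, threshold_k = 3,
                                 min_separation_s = 0.5) {
  n <- length(jerk)
  if (n == 0)
    abort_canegait("empty jerk series", "canegait_data_error")
  thr <- mean(jerk) + threshold_k * stats::sd(jerk)
  cand <- integer(0)
  if (n >= 3) {
    i <- 2:(n - 1)
    cand <- i[jerk[i] > jerk[i - 1] & jerk[i] >= jerk[i + 1] & jerk[i] > thr]
  }
  if (!length(cand))
    abort_canegait("no cane ground contact detected; trial unusable",
                   "canegait_no_contact_error")
  min_gap <- round(min_separation_s * sample_rate_hz)
  accepted <- integer(0)
  for (idx in cand[order(jerk[cand], decreasing = TRUE)]) {
    if (!length(accepted) || all(abs(accepted - idx) >= min_gap))
      accepted <- c(accepted, idx)
  }
  structure(sort(accepted), class = "contact_events",
            threshold = thr, min_separation_s = min_separation_s)
}

#' Extract the fixed-length analysis window
#'
#' Takes `window_len` samples starting at the first detected cane contact
#' (the study design uses 512 frames at 120 Hz) and re-expresses the contact
#' indices relative to the window. Trials too short for a full window are
#' excluded with a typed `canegait_short_trial_error`, mirroring the
#' exclusion of unmeasurable recordings.
#'
#' @param rec a (filtered) [imu_recording()].
#' @param contacts contact sample indices.
#' @param window_len window length in samples.
#' @return list with elements `recording` (the windowed recording),
#'   `contacts` (indices relative to the window, 1-based) and `offset`
#'   (index of the first window sample in the original recording).
#' @export
extract_analysis_window <- function(rec, contacts, window_len = 512) {
  n <- n_samples(rec)
  c0 <- contacts[1]
  if (c0 + window_len - 1 > n)
    abort_canegait(
      sprintf("trial too short: first contact at sample %d + %d-sample window exceeds %d samples",
              c0, window_len, n),
      "canegait_short_trial_error")
  idx <- c0:(c0 + window_len - 1)
  wrec <- rec
  wrec$acc <- rec$acc[idx, , drop = FALSE]
  wrec$gyro <- rec$gyro[idx, , drop = FALSE]
  wc <- contacts - c0 + 1L
  list(recording = wrec, contacts = wc[wc >= 1 & wc <= window_len],
       offset = c0)
}

#' Segment a window into gait cycles
#'
#' A gait cycle is the interval between two successive cane contacts,
#' expressed as half-open index intervals `[start, end)`; only complete
#' cycles inside the window are used.
#'
#' @param contacts contact indices inside the window (>= 2 required).
#' @param sample_rate_hz sampling rate.
#' @return data frame with columns `start` (inclusive), `end` (exclusive)
#'   and `duration_s`.
#' @export
segment_cycles <- function(contacts, sample_rate_hz) {
  if (length(contacts) < 2)
    abort_canegait("fewer than 2 contacts in window: no complete gait cycle",
                   "canegait_too_few_cycles_error")
  contacts <- as.integer(contacts)
  data.frame(
    start = contacts[-length(contacts)],
    end = contacts[-1],
    duration_s = diff(contacts) / sample_rate_hz)
}
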