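trial_csv_columns <- function() {
  c("time_s", "acc_vt", "acc_ap", "acc_ml", "gyr_vt", "gyr_ap", "gyr_ml")
}

#' Construct an IMU recording
#'
#' Holds one walking trial from the cane-mounted sensor: tri-axial
#' acceleration (m/s^2) and angular velocity (deg/s), axis order vertical
#' (VT), anteroposterior (AP), mediolateral (ML), at a fixed sample rate.
#' Channels are taken as already expressed along the anatomical axes; no
#' unit conversion or orientation correction is performed.
#'
#' @param trial_id,subject_id identifiers.
#' @param sample_rate_hz positive sampling rate (120 for the study design).
#' @param acc,gyro N x 3 numeric matrices, columns VT, AP, ML.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(trial_id, subject_id, sample_rate_hz, acc, gyro) {
  acc <- as.matrix(acc)
  gyro <- as.matrix(gyro)
  if (nrow(acc) < 2)
    abort_canegait("recording must contain at least 2 samples",
                   "canegait_data_error")
  if (!identical(dim(acc), dim(gyro)) || ncol(acc) != 3)
    abort_canegait("acc and gyro must be N x 3 matrices of identical size",
                   "canegait_data_error")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    abort_canegait("sample_rate_hz must be positive", "canegait_data_error")
  if (anyNA(acc) || anyNA(gyro))
    abort_canegait("recording contains missing samples", "canegait_data_error")
  colnames(acc) <- colnames(gyro) <- axis_names()
  structure(
    list(trial_id = as.character(trial_id),
         subject_id = as.character(subject_id),
         sample_rate_hz = as.numeric(sample_rate_hz),
         acc = acc, gyro = gyro),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> trial %s (subject %s): %d samples @ %g Hz (%.2f s)\n",
              x$trial_id, x$subject_id, nrow(x$acc), x$sample_rate_hz,
              nrow(x$acc) / x$sample_rate_hz))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$acc)

#' Read one trial CSV
#'
#' Expects a comma-separated, dot-decimal, UTF-8 file with a single header
#' row naming the seven columns `time_s, acc_vt, acc_ap, acc_ml, gyr_vt,
#' gyr_ap, gyr_ml`. The sample rate is inferred from the median time step
#' and, when a declared rate is supplied (e.g. from a cohort manifest),
#' checked against it within 1%.
#'
#' @param path file path.
#' @param trial_id,subject_id identifiers; default trial_id is the file stem.
#' @param declared_rate_hz optional declared sampling rate to check against.
#' @param rate_tol relative tolerance for the rate check.
#' @return an [imu_recording()].
#' @export
read_trial_csv <- function(path, trial_id = NULL, subject_id = NA,
                           declared_rate_hz = NULL, rate_tol = 0.01) {
  if (!file.exists(path))
    abort_canegait(sprintf("trial file not found: %s", path),
                   "canegait_format_error")
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(trial_csv_columns(), names(df))
  if (length(missing))
    abort_canegait(
      sprintf("trial file %s is missing column(s): %s",
              basename(path), paste(missing, collapse = ", ")),
      "canegait_format_error")
  df <- df[trial_csv_columns()]
  if (anyNA(df))
    abort_canegait(sprintf("trial file %s contains missing values",
                           basename(path)), "canegait_data_error")
  if (nrow(df) < 2)
    abort_canegait(sprintf("trial file %s has fewer than 2 samples",
                           basename(path)), "canegait_data_error")
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    abort_canegait(sprintf("trial file %s has a non-monotonic time column",
                           basename(path)), "canegait_data_error")
  fs <- 1 / stats::median(dt)
  if (!is.null(declared_rate_hz)) {
    if (abs(fs - declared_rate_hz) / declared_rate_hz > rate_tol)
      abort_canegait(
        sprintf("trial file %s: inferred rate %.3f Hz differs from declared %g Hz by more than %g%%",
                basename(path), fs, declared_rate_hz, 100 * rate_tol),
        "canegait_rate_error")
    fs <- declared_rate_hz
  }
  imu_recording(
    trial_id = trial_id %||% sub("\\.[^.]*$", "", basename(path)),
    subject_id = subject_id,
    sample_rate_hz = fs,
    acc = as.matrix(df[c("acc_vt", "acc_ap", "acc_ml")]),
    gyro = as.matrix(df[c("gyr_vt", "gyr_ap", "gyr_ml")]))
}

#' Write one trial CSV
#'
#' Inverse of [read_trial_csv()]; the time column is reconstructed as
#' `(0:(N-1)) / sample_rate_hz`.
#'
#' @param rec an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- n_samples(rec)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / rec$sample_rate_hz,
    acc_vt = rec$acc[, 1], acc_ap = rec$acc[, 2], acc_ml = rec$acc[, 3],
    gyr_vt = rec$gyro[, 1], gyr_ap = rec$gyro[, 2], gyr_ml = rec$gyro[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' One row per trial with columns `subject_id`, `trial_id`, `trial_file`,
#' `frail_label` (values `frail`/`robust`); demographic columns are carried
#' through untouched when present.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest a manifest data frame.
#' @export
validate_manifest <- function(manifest) {
  need <- c("subject_id", "trial_id", "trial_file", "frail_label")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    abort_canegait(sprintf("manifest is missing column(s): %s",
                           paste(missing, collapse = ", ")),
                   "canegait_format_error")
  if (anyDuplicated(manifest$trial_file))
    abort_canegait("manifest trial_file values must be unique",
                   "canegait_data_error")
  if (anyNA(manifest$frail_label) ||
      !all(manifest$frail_label %in% c("frail", "robust")))
    abort_canegait("frail_label must be 'frail' or 'robust' with no missing values",
                   "canegait_data_error")
  manifest
}

#' Write a cohort manifest CSV
#'
#' @param manifest a validated manifest data frame.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table CSV
#'
#' One row per trial: `trial_id`, `subject_id`, `frail_label`, then the ten
#' features of [canegait_features()]. Numeric values are written with 12
#' significant digits so the table round-trips through
#' [read_feature_table()] to better than 1e-9 relative error.
#'
#' @param features a feature-table data frame.
#' @param path output path.
#' @export
write_feature_table <- function(features, path) {
  need <- c("trial_id", "subject_id", "frail_label", canegait_features())
  missing <- setdiff(need, names(features))
  if (length(missing))
    abort_canegait(sprintf("feature table is missing column(s): %s",
                           paste(missing, collapse = ", ")),
                   "canegait_format_error")
  if (nrow(features) == 0)
    abort_canegait("feature table is empty", "canegait_data_error")
  if (anyDuplicated(features$trial_id))
    abort_canegait("duplicate trial_id in feature table",
                   "canegait_data_error")
  out <- features[need]
  for (nm in canegait_features())
    out[[nm]] <- formatC(out[[nm]], digits = 12, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path file path.
#' @return a feature-table data frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("trial_id", "subject_id", "frail_label", canegait_features())
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort_canegait(sprintf("feature table %s is missing column(s): %s",
                           basename(path), paste(missing, collapse = ", ")),
                   "canegait_format_error")
  df
}
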