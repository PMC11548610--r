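#' Default run configuration
#'
#' Returns the configuration used throughout the pipeline: a fourth-order
#' 10 Hz low-pass filter, jerk-peak contact detection at mean + 3 sd with a
#' 0.5 s refractory period, a 512-sample analysis window, a 0.5-10 Hz band
#' for the mean power frequency, and tenfold cross-validation. Model
#' hyperparameters carry the fixed values used by the study design: at most
#' 5 splits for the decision tree and 243 logistic-boosting rounds at
#' learning rate 0.59256 for the boosted ensemble.
#'
#' @return an object of class `run_config` (a named list).
#' @export
default_run_config <- function() {
  cfg <- list(
    filter = list(cutoff_hz = 10, order = 4L),
    contacts = list(threshold_k = 3, min_separation_s = 0.5),
    window_len_samples = 512L,
    mpf_band_hz = c(0.5, 10),
    demean_window = TRUE,
    positive_class = "frail",
    cv = list(n_folds = 10L, seed = 1L, mode = "trial", search_budget = 30L),
    models = list(
      dt = list(max_splits = 5L),
      lda = list(),
      knn = list(k = 5L),
      svm = list(cost = 1, gamma = NULL),
      boost = list(n_rounds = 243L, learning_rate = 0.59256, max_depth = 1L)
    )
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` list.
#' @return `cfg`, invisibly unchanged, or a typed error.
#' @export
validate_run_config <- function(cfg) {
  if (!is_power_of_two(cfg$window_len_samples))
    abort_canegait(
      sprintf("window_len_samples (%s) must be a power of two",
              cfg$window_len_samples),
      "canegait_config_error")
  band <- cfg$mpf_band_hz
  if (length(band) != 2 || !is.numeric(band) || band[1] >= band[2])
    abort_canegait("mpf_band_hz must be c(lower, upper) with lower < upper",
                   "canegait_config_error")
  if (cfg$filter$cutoff_hz <= 0 || cfg$filter$order < 1)
    abort_canegait("filter cutoff must be positive and order >= 1",
                   "canegait_config_error")
  if (cfg$contacts$min_separation_s <= 0)
    abort_canegait("contact min_separation_s must be positive",
                   "canegait_config_error")
  if (cfg$cv$n_folds < 2)
    abort_canegait("cv n_folds must be >= 2", "canegait_config_error")
  if (!cfg$cv$mode %in% c("trial", "subject"))
    abort_canegait("cv mode must be 'trial' or 'subject'",
                   "canegait_config_error")
  invisible(cfg)
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(defaults))
      abort_canegait(
        sprintf("unknown configuration key '%s'; valid keys here: %s",
                here, paste(names(defaults), collapse = ", ")),
        "canegait_config_error")
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration from YAML or JSON
#'
#' Keys absent from the document take the defaults of
#' [default_run_config()]; unknown keys are rejected with a message listing
#' the valid keys at that level.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    abort_canegait(sprintf("config file not found: %s", path),
                   "canegait_format_error")
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}
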