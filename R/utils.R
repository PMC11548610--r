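`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a typed canegait error
#'
#' All recoverable pipeline failures (unusable trials, malformed files,
#' degenerate samples) are raised as classed conditions so that callers can
#' catch them selectively with `tryCatch(..., canegait_error = )` or by the
#' specific subclass.
#'
#' @param msg message text.
#' @param class condition subclass, e.g. `"canegait_no_contact_error"`.
#' @param call call to attach.
#' @keywords internal
abort_canegait <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "canegait_error"), call = call))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded generator functions do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific sub-seed from a top-level seed
#'
#' One user-facing seed is expanded into named substreams (one per pipeline
#' stage) so that each stage is independently reproducible. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed top-level integer seed.
#' @param stage character stage name.
#' @param index optional replicate index within the stage.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) + 1000003 * h + 7919 * as.numeric(index)) %%
               2147483647)
}

is_power_of_two <- function(n) {
  n <- as.integer(n)
  !is.na(n) && n >= 1L && bitwAnd(n, n - 1L) == 0L
}

#' Names of the ten trial-level features
#'
#' Order: RMS of acceleration (VT, AP, ML), mean power frequency (VT, AP,
#' ML), peak angular velocity (VT, AP, ML), stride time.
#'
#' @return character vector of length 10.
#' @export
canegait_features <- function() {
  c("rms_vt", "rms_ap", "rms_ml",
    "mpf_vt", "mpf_ap", "mpf_ml",
    "pav_vt", "pav_ap", "pav_ml",
    "stride_time_s")
}

axis_names <- function() c("vt", "ap", "ml")
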