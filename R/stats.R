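#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] with typed errors for
#' out-of-range or degenerate samples. Used as a screen only: the group
#' comparison proceeds nonparametrically regardless of its outcome.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000)
    abort_canegait("Shapiro-Wilk requires 3 <= n <= 5000",
                   "canegait_data_error")
  if (diff(range(x)) == 0)
    abort_canegait("all values identical: Shapiro-Wilk W undefined",
                   "canegait_degenerate_error")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p_value = st$p.value)
}

#' Mann-Whitney U test with rank-biserial effect size inputs
#'
#' Computes U from rank sums with midranks for ties, the standardized
#' statistic Z from the tie-corrected normal approximation, and a
#' two-sided p-value. Z is reported without continuity correction (it
#' feeds the effect size r = |Z| / sqrt(N)); the p-value applies a 0.5
#' continuity correction so that it tracks the exact permutation
#' distribution closely even at small samples (set `continuity = FALSE`
#' for the plain large-sample p). With `exact = TRUE` and a feasible
#' enumeration size, the exact two-sided permutation p-value (tail
#' inclusive of the observed statistic) is computed by full enumeration of
#' the group labelings.
#'
#' @param x,y numeric samples for the two groups.
#' @param continuity apply the continuity correction to the p-value.
#' @param exact also compute the exact enumeration p-value (small n only).
#' @return list with `U` (reported as min(U1, U2)), `U1`, `Z`, `p_value`,
#'   `n1`, `n2`, and `p_exact` when requested.
#' @export
mann_whitney_u <- function(x, y, continuity = TRUE, exact = FALSE) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1)
    abort_canegait("both groups must be non-empty", "canegait_data_error")
  N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2

  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0)
    abort_canegait("all observations tied across both groups",
                   "canegait_degenerate_error")
  sigma <- sqrt(sigma2)

  z <- (U1 - mu) / sigma
  z_p <- (abs(U1 - mu) - if (continuity) 0.5 else 0) / sigma
  p <- min(1, 2 * stats::pnorm(-max(0, z_p)))

  out <- list(U = min(U1, U2), U1 = U1, Z = z, p_value = p, n1 = n1, n2 = n2)
  if (exact) {
    if (choose(N, n1) > 2e5)
      abort_canegait("exact enumeration infeasible for these sample sizes",
                     "canegait_data_error")
    cmb <- utils::combn(N, n1)
    U1_all <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    out$p_exact <- mean(abs(U1_all - mu) >= abs(U1 - mu) - 1e-9)
  }
  out
}

#' Rank-based effect size r
#'
#' r = |Z| / sqrt(N) with N the total sample size across both groups.
#'
#' @param z standardized Mann-Whitney statistic.
#' @param n_total total number of observations.
#' @return r in `[0, 1]` (values are clamped at 1 for pathological inputs).
#' @export
effect_size_r <- function(z, n_total) {
  if (n_total < 2)
    abort_canegait("n_total must be >= 2", "canegait_data_error")
  min(1, abs(z) / sqrt(n_total))
}

#' Magnitude class of an effect size
#'
#' Bands with half-open intervals, left endpoint inclusive: negligible
#' (r < 0.1), small (0.1 <= r < 0.3), moderate (0.3 <= r < 0.5), large
#' (0.5 <= r).
#'
#' @param r effect size(s), non-negative.
#' @return character vector of magnitude classes.
#' @export
classify_effect <- function(r) {
  if (any(r < 0))
    abort_canegait("effect size r must be non-negative",
                   "canegait_data_error")
  as.character(cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
                   labels = c("negligible", "small", "moderate", "large"),
                   right = FALSE))
}

#' Compare every feature between the frail and robust groups
#'
#' For each of the ten trial features: Shapiro-Wilk screen per group,
#' Mann-Whitney U with Z and two-sided p, effect size r = |Z| / sqrt(N)
#' and its magnitude class, with significance flagged at `alpha`. No
#' multiple-testing correction is applied across the ten features (the
#' per-feature comparisons are reported as-is; treat the family-wise rate
#' as a caveat).
#'
#' @param features feature-table data frame (from
#'   [extract_cohort_features()] or [read_feature_table()]).
#' @param label_col name of the group-label column.
#' @param positive label treated as group 1 (default `"frail"`).
#' @param feature_cols features to compare.
#' @param alpha significance level (default 0.05).
#' @return object of class `group_comparison`: list with `comparisons` and
#'   `normality` data frames.
#' @export
compare_groups <- function(features, label_col = "frail_label",
                           positive = "frail",
                           feature_cols = canegait_features(),
                           alpha = 0.05) {
  if (!label_col %in% names(features))
    abort_canegait(sprintf("label column '%s' not found", label_col),
                   "canegait_format_error")
  lab <- features[[label_col]]
  g1 <- lab == positive
  if (!any(g1) || all(g1))
    abort_canegait("both groups must be non-empty", "canegait_data_error")

  comp <- list()
  norm <- list()
  for (f in feature_cols) {
    x <- features[[f]][g1]
    y <- features[[f]][!g1]
    mw <- mann_whitney_u(x, y)
    r <- effect_size_r(mw$Z, mw$n1 + mw$n2)
    comp[[f]] <- data.frame(
      feature = f, n_frail = mw$n1, n_robust = mw$n2,
      median_frail = stats::median(x), median_robust = stats::median(y),
      U = mw$U, Z = mw$Z, p_value = mw$p_value,
      r = r, magnitude = classify_effect(r),
      significant = mw$p_value < alpha)
    for (grp in c(positive, "other")) {
      v <- if (grp == positive) x else y
      sw <- tryCatch(shapiro_wilk(v), canegait_error = function(e)
        list(W = NA_real_, p_value = NA_real_))
      norm[[paste(f, grp)]] <- data.frame(
        feature = f, group = if (grp == positive) positive else "reference",
        W = sw$W, p_value = sw$p_value)
    }
  }
  structure(list(comparisons = do.call(rbind, c(comp, make.row.names = FALSE)),
                 normality = do.call(rbind, c(norm, make.row.names = FALSE)),
                 alpha = alpha, positive = positive),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-group feature comparison (positive class: %s, alpha = %g)\n",
              x$positive, x$alpha))
  df <- x$comparisons
  df$p_value <- signif(df$p_value, 3)
  df$r <- round(df$r, 2)
  print(df[c("feature", "median_frail", "median_robust", "U", "Z",
             "p_value", "r", "magnitude", "significant")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
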