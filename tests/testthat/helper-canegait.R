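# shared fixtures and independent oracles

# direct O(L^2) DFT, independent of stats::fft
brute_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)), complex(1))
}

# independent Mann-Whitney exact two-sided p by full enumeration
# (rank sums recomputed from scratch; tail inclusive of the observed value)
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (length(y)) / 2
  U1_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(N, n1)
  U1_all <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(U1_all - mu) >= abs(U1_obs - mu) - 1e-9)
}

# tiny well-formed trial CSV on disk; returns its path
write_tiny_trial <- function(path, n = 3, fs = 120) {
  df <- data.frame(time_s = (0:(n - 1)) / fs,
                   acc_vt = 9.81 + seq_len(n) / 10,
                   acc_ap = seq_len(n) / 20, acc_ml = -seq_len(n) / 30,
                   gyr_vt = seq_len(n), gyr_ap = -seq_len(n),
                   gyr_ml = seq_len(n) / 2)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# feature table with two Gaussian clusters separated by `gap` sd
make_cluster_table <- function(n_pos = 37, n_neg = 94, gap = 5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- matrix(rnorm(n * 10), n, 10)
  x[seq_len(n_pos), ] <- x[seq_len(n_pos), ] + gap
  ft <- as.data.frame(x)
  names(ft) <- canegait_features()
  ft$trial_id <- sprintf("T%03d", seq_len(n))
  ft$subject_id <- sprintf("S%03d", seq_len(n))
  ft$frail_label <- c(rep("frail", n_pos), rep("robust", n_neg))
  ft
}

# label-shuffled null feature table (identical group distributions)
make_null_table <- function(n_pos = 37, n_neg = 94, seed = 1) {
  ft <- make_cluster_table(n_pos, n_neg, gap = 0, seed = seed)
  ft
}
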