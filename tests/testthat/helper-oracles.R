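# Independent, deliberately naive reference implementations of the window
# statistics, written from the textbook definitions (loops, explicit sorting)
# rather than by calling the package's own code paths.

oracle_mean <- function(a) {
  s <- 0
  for (v in a) s <- s + v
  s / length(a)
}

oracle_variance_unnorm <- function(a) {
  mu <- oracle_mean(a)
  s <- 0
  for (v in a) s <- s + (v - mu)^2
  s
}

oracle_std_pop <- function(a) sqrt(oracle_variance_unnorm(a) / length(a))

oracle_median <- function(a) {
  srt <- sort(a)
  n <- length(a)
  if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
}

oracle_mad <- function(a) {
  m <- oracle_median(a)
  oracle_median(abs(a - m))
}

oracle_zcr_centered <- function(a) {
  x <- a - oracle_mean(a)
  cnt <- 0
  for (i in 2:length(x)) if (x[i] * x[i - 1] < 0) cnt <- cnt + 1
  cnt
}

oracle_entropy <- function(a, bins = 10) {
  lo <- min(a); hi <- max(a)
  if (lo == hi) return(0)
  counts <- numeric(bins)
  width <- (hi - lo) / bins
  for (v in a) {
    b <- floor((v - lo) / width) + 1
    if (b > bins) b <- bins
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / length(a)
      h <- h - p * log(p)
    }
  }
  h
}

oracle_kurtosis <- function(a) {
  mu <- oracle_mean(a)
  sig <- oracle_std_pop(a)
  if (sig == 0) return(0)
  oracle_mean((a - mu)^4) / sig^4
}

oracle_skewness <- function(a) {
  mu <- oracle_mean(a)
  sig <- oracle_std_pop(a)
  if (sig == 0) return(0)
  oracle_mean((a - mu)^3) / sig^3
}

oracle_cov_pop <- function(x, y) {
  mx <- oracle_mean(x); my <- oracle_mean(y)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - mx) * (y[i] - my)
  s / length(x)
}

# check every feature of one window matrix against the oracles
expect_features_match_oracle <- function(w, rtol = 1e-9) {
  fv <- extract_features(w)
  for (ch in colnames(w)) {
    a <- w[, ch]
    exp_vals <- c(
      mean = oracle_mean(a), variance = oracle_variance_unnorm(a),
      std = oracle_std_pop(a), max = max(a), min = min(a),
      range = max(a) - min(a), zcr = oracle_zcr_centered(a),
      median = oracle_median(a), mad = oracle_mad(a),
      entropy = oracle_entropy(a), kurtosis = oracle_kurtosis(a),
      skewness = oracle_skewness(a))
    got <- fv[paste0(names(exp_vals), "_", ch)]
    expect_equal(unname(got), unname(exp_vals), tolerance = rtol)
  }
  expect_equal(fv[["cov_acc_x_acc_y"]], oracle_cov_pop(w[, "acc_x"], w[, "acc_y"]),
               tolerance = rtol)
  expect_equal(fv[["cov_acc_x_acc_z"]], oracle_cov_pop(w[, "acc_x"], w[, "acc_z"]),
               tolerance = rtol)
  expect_equal(fv[["cov_acc_y_acc_z"]], oracle_cov_pop(w[, "acc_y"], w[, "acc_z"]),
               tolerance = rtol)
}

# quick random window matrix (not via the generator)
random_window <- function(n = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cbind(acc_x = rnorm(n), acc_y = rnorm(n), acc_z = rnorm(n) + 9.81,
             baro = 1013 + rnorm(n, 0, 0.05))
  cbind(m[, 1:3, drop = FALSE],
        acc_all = sqrt(m[, 1]^2 + m[, 2]^2 + m[, 3]^2),
        baro = m[, 4])
}

# small labelled stream for I/O and windowing tests
toy_stream <- function(n = 125, seed = 1, label = NULL) {
  set.seed(seed)
  sensor_stream(t = (seq_len(n) - 1) / 50,
                acc_x = rnorm(n, 0, 0.1), acc_y = rnorm(n, 0, 0.1),
                acc_z = rnorm(n, 9.81, 0.1),
                baro = rep(1013.25, n),
                label = label)
}
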