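#' Acceleration magnitude
#'
#' The orientation-free acceleration magnitude
#' `acc_all = sqrt(acc_x^2 + acc_y^2 + acc_z^2)`, the channel whose windowed
#' standard deviation drives the STD-TA transition detector.
#'
#' @param acc_x,acc_y,acc_z numeric accelerations in m/s^2.
#' @return Non-negative numeric vector, m/s^2.
#' @export
#' @examples
#' acc_magnitude(3, 4, 0)  # 5
acc_magnitude <- function(acc_x, acc_y, acc_z) {
  sqrt(acc_x^2 + acc_y^2 + acc_z^2)
}

#' Per-window statistical features
#'
#' Computes twelve statistics per channel over the five channels
#' `acc_x, acc_y, acc_z, acc_all, baro`, plus the three pairwise accelerometer
#' covariances (63 features by default). The per-channel statistics are:
#'
#' * `mean`; `variance` = sum((a - mu)^2), the unnormalised sum of squared
#'   deviations; `std` = sqrt(sum((a - mu)^2)/n), the population standard
#'   deviation — the two printed forms are kept as printed, so
#'   `variance = n * std^2`;
#' * `max`, `min`, `range`;
#' * `zcr`: zero-crossing rate. The default (`zcr = "centered"`) counts sign
#'   changes of the mean-centred channel; `zcr = "printed"` instead counts
#'   samples greater than zero, which is degenerate (constant `n`) on the
#'   always-positive `acc_all` channel;
#' * `median`; `mad` = median(|a - median(a)|);
#' * `entropy`: information entropy -sum(p * log p) over `entropy_bins`
#'   equal-width histogram bins spanning `[min, max]` of the window, natural
#'   log, with 0*log 0 = 0; a constant window has entropy 0;
#' * `kurtosis` = E[(a - mu)^4] / sigma^4 and `skewness` = E[(a - mu)^3] /
#'   sigma^3 with population sigma; both are 0 by convention when sigma = 0.
#'
#' @param w numeric matrix as returned by [window_matrix()] (rows = frames,
#'   named columns = channels), at least 2 rows.
#' @param channels channels to featurise; set
#'   `channels = c("acc_x","acc_y","acc_z","baro")` to drop the derived
#'   magnitude channel.
#' @param zcr `"centered"` (default) or `"printed"`, see above.
#' @param entropy_bins number of histogram bins for the entropy feature.
#' @return Named numeric feature vector (`<stat>_<channel>` plus
#'   `cov_acc_x_acc_y`, `cov_acc_x_acc_z`, `cov_acc_y_acc_z`).
#' @export
extract_features <- function(w, channels = colnames(w),
                             zcr = c("centered", "printed"),
                             entropy_bins = 10L) {
  zcr <- match.arg(zcr)
  n <- nrow(w)
  if (is.null(n) || n < 2L) stop("a window needs at least 2 frames")
  stats_one <- function(a) {
    mu <- mean(a)
    dev <- a - mu
    ssq <- sum(dev^2)
    sigma <- sqrt(ssq / n)
    med <- stats::median(a)
    c(mean = mu,
      variance = ssq,
      std = sigma,
      max = max(a),
      min = min(a),
      range = max(a) - min(a),
      zcr = if (zcr == "printed") sum(a > 0) else {
        x <- dev
        sum(x[-1] * x[-n] < 0)
      },
      median = med,
      mad = stats::median(abs(a - med)),
      entropy = window_entropy(a, entropy_bins),
      kurtosis = if (sigma > 0) mean(dev^4) / sigma^4 else 0,
      skewness = if (sigma > 0) mean(dev^3) / sigma^3 else 0)
  }
  vals <- unlist(lapply(channels, function(ch) {
    s <- stats_one(w[, ch])
    names(s) <- paste0(names(s), "_", ch)
    s
  }))
  pairs <- list(c("acc_x", "acc_y"), c("acc_x", "acc_z"), c("acc_y", "acc_z"))
  covs <- vapply(pairs, function(p) {
    x <- w[, p[1]]; y <- w[, p[2]]
    sum((x - mean(x)) * (y - mean(y))) / n
  }, numeric(1))
  names(covs) <- vapply(pairs, function(p) paste0("cov_", p[1], "_", p[2]), "")
  out <- c(vals, covs)
  if (any(!is.finite(out))) stop("non-finite feature value")
  out
}

# Histogram entropy: equal-width bins over [min, max]; constant window -> 0.
window_entropy <- function(a, bins = 10L) {
  r <- range(a)
  if (r[1] == r[2]) return(0)
  cuts <- seq(r[1], r[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(a, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts / length(a)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Feature matrix for every window of a stream
#'
#' Runs [sliding_windows()] and [extract_features()] over a whole stream.
#'
#' @inheritParams sliding_windows
#' @param ... passed to [extract_features()].
#' @return Numeric matrix, one row per window, with attributes `window_start`
#'   (0-based frame indices), `truth` and `segment` (when the stream is
#'   labelled), `size` and `step`.
#' @export
feature_matrix <- function(stream, size = 50L, step = 25L, ...) {
  ws <- sliding_windows(stream, size = size, step = step)
  rows <- lapply(ws$start, function(s0)
    extract_features(window_matrix(stream, s0, size), ...))
  fm <- do.call(rbind, rows)
  if (is.null(fm)) fm <- matrix(numeric(0), 0, 0)
  attr(fm, "window_start") <- ws$start
  if (!is.null(ws$truth)) attr(fm, "truth") <- ws$truth
  if (!is.null(ws$segment)) attr(fm, "segment") <- ws$segment
  attr(fm, "size") <- attr(ws, "size")
  attr(fm, "step") <- attr(ws, "step")
  fm
}

#' STD series of the acceleration magnitude
#'
#' Extracts the per-window population standard deviation of `acc_all` — the
#' raw trend signal that the STD-TA state machine analyses.
#'
#' @param fm feature matrix from [feature_matrix()] (or any matrix with an
#'   `std_acc_all` column).
#' @return Numeric vector, one STD value per window.
#' @export
std_series <- function(fm) {
  if (!"std_acc_all" %in% colnames(fm)) stop("no std_acc_all feature column")
  unname(fm[, "std_acc_all"])
}

#' Export a feature matrix as CSV
#'
#' @param fm feature matrix from [feature_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(window_start = attr(fm, "window_start"), fm,
                   check.names = FALSE)
  if (!is.null(attr(fm, "truth"))) df$truth <- attr(fm, "truth")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
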