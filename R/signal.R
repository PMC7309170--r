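#' Construct a synchronised sensor stream
#'
#' A sensor stream holds time-stamped, synchronised samples of a tri-axial
#' accelerometer (nominal 50 Hz, m/s^2) and a barometer already upsampled to
#' the accelerometer grid (hPa), with an optional per-frame ground-truth
#' activity label and an optional segment id linking frames to the schedule
#' that generated them.
#'
#' @param t numeric, seconds since stream start; strictly increasing,
#'   non-negative.
#' @param acc_x,acc_y,acc_z numeric acceleration channels in m/s^2.
#' @param baro numeric barometric pressure in hPa, one value per frame.
#' @param label optional character/factor per-frame activity label.
#' @param segment optional integer per-frame segment id.
#' @return A data.frame of class `"sensor_stream"` with columns
#'   `t, acc_x, acc_y, acc_z, baro` and optionally `label`, `segment`.
#' @export
sensor_stream <- function(t, acc_x, acc_y, acc_z, baro,
                          label = NULL, segment = NULL) {
  n <- length(t)
  if (!all(lengths(list(acc_x, acc_y, acc_z, baro)) == n)) {
    stop("all channels must have the same length as t")
  }
  num <- list(t = t, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z, baro = baro)
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || any(!is.finite(num[[nm]]))) {
      stop("channel '", nm, "' must be finite numeric")
    }
  }
  if (any(t < 0)) stop("timestamps must be non-negative")
  if (n > 1 && any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  df <- data.frame(t = t, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
                   baro = baro)
  if (!is.null(label)) {
    if (length(label) != n) stop("labels must have one entry per frame")
    df$label <- as.character(label)
  }
  if (!is.null(segment)) {
    if (length(segment) != n) stop("segment ids must have one entry per frame")
    df$segment <- as.integer(segment)
  }
  class(df) <- c("sensor_stream", "data.frame")
  df
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d frames, %.1f s%s\n", nrow(x),
              if (nrow(x)) x$t[nrow(x)] - x$t[1] else 0,
              if ("label" %in% names(x)) ", labelled" else ""))
  if ("label" %in% names(x)) {
    tab <- table(x$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a sensor stream from delimited text
#'
#' Expects a header row with columns `t, acc_x, acc_y, acc_z, baro` plus
#' optional `label` and `segment` (UTF-8, `.` decimal separator). A second
#' dialect keeps the raw 5 Hz barometer in a separate two-column file
#' (`t, baro`); it is aligned to the accelerometer grid on load by
#' sample-and-hold upsampling (each pressure reading repeated ten times).
#'
#' @param path CSV file with at least the accelerometer columns.
#' @param baro_path optional CSV file holding the raw 5 Hz barometer; when
#'   given, `path` needs no `baro` column.
#' @param upsample_factor accelerometer samples per barometer sample
#'   (default 10, i.e. 50 Hz vs 5 Hz).
#' @return A [sensor_stream()].
#' @export
read_stream <- function(path, baro_path = NULL, upsample_factor = 10L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "acc_x", "acc_y", "acc_z", if (is.null(baro_path)) "baro")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  for (nm in intersect(c("t", "acc_x", "acc_y", "acc_z", "baro"), names(df))) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at data line %d: '%s'",
                     nm, bad[1], v[bad[1]]))
      }
      df[[nm]] <- num
    }
    if (anyNA(df[[nm]])) {
      stop(sprintf("missing value in column '%s' at data line %d",
                   nm, which(is.na(df[[nm]]))[1]))
    }
  }
  if (!is.null(baro_path)) {
    if (!file.exists(baro_path)) stop("no such file: ", baro_path)
    bdf <- utils::read.csv(baro_path, stringsAsFactors = FALSE)
    if (!"baro" %in% names(bdf)) stop("missing column(s) in ", baro_path, ": baro")
    baro <- upsample_barometer(as.numeric(bdf$baro), upsample_factor)
    n <- min(nrow(df), length(baro))
    df <- df[seq_len(n), , drop = FALSE]
    df$baro <- baro[seq_len(n)]
  }
  sensor_stream(df$t, df$acc_x, df$acc_y, df$acc_z, df$baro,
                label = df$label, segment = df$segment)
}

#' Write a sensor stream to CSV at full precision
#'
#' Numeric channels are written with 17 significant digits so that a
#' write/read round trip reproduces every double bit-identically.
#'
#' @param stream a [sensor_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  num_cols <- c("t", "acc_x", "acc_y", "acc_z", "baro")
  out <- as.data.frame(lapply(stream[num_cols], function(v) sprintf("%.17g", v)),
                       stringsAsFactors = FALSE)
  for (nm in intersect(c("label", "segment"), names(stream))) out[[nm]] <- stream[[nm]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample-and-hold barometer upsampling
#'
#' Aligns the 5 Hz barometer to the 50 Hz accelerometer grid by repeating each
#' pressure reading `factor` times in order, so that every block of `factor`
#' accelerometer samples shares the same barometer value. No interpolation is
#' performed.
#'
#' @param baro numeric vector of raw barometer samples.
#' @param factor repetitions per sample (default 10).
#' @return Numeric vector of length `factor * length(baro)`.
#' @export
#' @examples
#' upsample_barometer(c(1013.2, 1013.1))
upsample_barometer <- function(baro, factor = 10L) {
  stopifnot(is.numeric(baro), factor >= 1)
  if (!length(baro)) return(numeric(0))
  rep(baro, each = as.integer(factor))
}

#' Segment a stream into overlapping windows
#'
#' Fixed-size sliding windows with constant step: window `i` covers frames
#' `[start_i, start_i + size)` with `start_i = (i-1) * step` (0-based starts).
#' Frames beyond the last full window are dropped. When the stream carries
#' per-frame truth labels, each window is labelled by its majority frame
#' label; ties break toward `"Transition"` if present, otherwise toward the
#' lowest canonical label index. A window containing any transition frames
#' also records which segment they came from.
#'
#' @param stream a [sensor_stream()].
#' @param size window length in frames (default 50, i.e. 1 s at 50 Hz).
#' @param step stride in frames (default 25, i.e. 0.5 s overlap).
#' @return A data.frame of class `"window_set"` with columns `start` (0-based
#'   frame index) and, when the stream is labelled, `truth` and `segment`;
#'   attributes `size` and `step`.
#' @export
#' @examples
#' s <- sensor_stream(t = (0:124)/50, acc_x = rnorm(125), acc_y = rnorm(125),
#'                    acc_z = rnorm(125) + 9.81, baro = rep(1013, 125))
#' sliding_windows(s)$start  # 0 25 50 75
sliding_windows <- function(stream, size = 50L, step = 25L) {
  size <- as.integer(size); step <- as.integer(step)
  if (is.na(size) || size < 1L) stop("size must be a positive integer")
  if (is.na(step) || step < 1L || step > size) stop("step must satisfy 1 <= step <= size")
  n <- nrow(stream)
  k <- if (n >= size) (n - size) %/% step + 1L else 0L
  starts <- if (k > 0L) (seq_len(k) - 1L) * step else integer(0)
  out <- data.frame(start = starts)
  if ("label" %in% names(stream) && k > 0L) {
    lv <- activity_levels(transition = TRUE)
    lab <- character(k); seg <- rep(NA_integer_, k)
    for (i in seq_len(k)) {
      idx <- starts[i] + seq_len(size)
      out_i <- window_majority_label(stream$label[idx], lv)
      lab[i] <- out_i
      if ("segment" %in% names(stream)) {
        use <- if (out_i == "Transition") stream$label[idx] == "Transition"
               else stream$label[idx] == out_i
        segs <- stream$segment[idx][use]
        seg[i] <- as.integer(names(which.max(table(segs))))
      }
    }
    out$truth <- lab
    if ("segment" %in% names(stream)) out$segment <- seg
  }
  structure(out, size = size, step = step,
            class = c("window_set", "data.frame"))
}

# Majority frame label; ties break toward Transition, then lowest canonical
# label index.
window_majority_label <- function(labels, lv = activity_levels(TRUE)) {
  tab <- table(factor(labels, levels = lv))
  top <- names(tab)[tab == max(tab)]
  if ("Transition" %in% top) "Transition" else top[1]
}

#' Extract one window's channel matrix
#'
#' Returns the raw channels of the window starting at 0-based frame index
#' `start`, plus the derived acceleration magnitude channel `acc_all`.
#'
#' @param stream a [sensor_stream()].
#' @param start 0-based first frame index of the window.
#' @param size window length in frames.
#' @return Numeric matrix `size x 5` with columns
#'   `acc_x, acc_y, acc_z, acc_all, baro`.
#' @export
window_matrix <- function(stream, start, size = 50L) {
  idx <- start + seq_len(size)
  if (start < 0 || max(idx) > nrow(stream)) stop("window out of range")
  m <- cbind(acc_x = stream$acc_x[idx], acc_y = stream$acc_y[idx],
             acc_z = stream$acc_z[idx],
             acc_all = acc_magnitude(stream$acc_x[idx], stream$acc_y[idx],
                                     stream$acc_z[idx]),
             baro = stream$baro[idx])
  m
}
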