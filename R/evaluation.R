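#' Confusion matrix over activity classes
#'
#' Rows are ground truth, columns are predictions.
#'
#' @param truth,pred label vectors of equal length.
#' @param levels ordered class list; defaults to the canonical nine classes
#'   restricted to those present.
#' @return Integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (is.null(levels)) {
    canon <- activity_levels(transition = TRUE)
    seen <- unique(c(truth, pred))
    levels <- if (all(seen %in% canon)) canon[canon %in% seen] else sort(seen)
  }
  bad <- setdiff(unique(c(truth, pred)), levels)
  if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- unclass(m)
  dimnames(m) <- list(truth = levels, pred = levels)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class recall
#'
#' `recall[i] = counts[i, i] / rowsum[i]`; classes with no truth windows are
#' reported as `NA`.
#'
#' @param cm a [confusion_matrix()] (any square count matrix works).
#' @return Named numeric vector of recalls in `[0, 1]`.
#' @export
recall_per_class <- function(cm) {
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, diag(as.matrix(cm)) / rs, NA_real_)
  names(out) <- rownames(cm)
  out
}

#' @export
print.confusion_matrix <- function(x, digits = 6, ...) {
  m <- as.matrix(unclass(x))
  disp <- cbind(m, SUM = rowSums(m))
  rec <- recall_per_class(x)
  out <- data.frame(disp, Recall = round(rec, digits), check.names = FALSE)
  print(out, ...)
  invisible(x)
}

#' Reference confusion matrices from a published evaluation
#'
#' Printed nine-class confusion matrices (eight basic activities A01--A08
#' plus the pooled transition class A09) from a published smartphone HAR
#' evaluation of four methods on a common real test set: a flat 9-class SVM,
#' a flat 9-class KNN, the STD-TA pipeline, and a CUSUM change-point
#' baseline. Shipped as plain-text tables under `inst/extdata/` together
#' with the published SUM and Recall columns, so that the package's recall
#' arithmetic can be validated against independently printed values.
#'
#' @param method one of `"svm"`, `"knn"`, `"stdta"`, `"cusum"`.
#' @return List with `counts` (a 9 x 9 [confusion_matrix()]), `sum` and
#'   `recall` (the published per-class values).
#' @export
reference_confusion <- function(method = c("svm", "knn", "stdta", "cusum")) {
  method <- match.arg(method)
  path <- system.file("extdata", paste0("reference_confusion_", method, ".csv"),
                      package = "stdta", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  cls <- df$class
  counts <- as.matrix(df[, cls, drop = FALSE])
  rownames(counts) <- cls
  dimnames(counts) <- list(truth = cls, pred = cls)
  list(counts = structure(counts, class = c("confusion_matrix", "matrix")),
       sum = stats::setNames(df$SUM, cls),
       recall = stats::setNames(df$Recall, cls))
}

#' Compare transition-recognition methods on labelled streams
#'
#' Runs each fitted model over the same labelled streams, scores every window
#' against its ground truth (majority label, ties to the transition class —
#' no grace period around transition boundaries), and tabulates one
#' nine-class confusion matrix and recall vector per method.
#'
#' @param streams a labelled [sensor_stream()], a list of them, or a
#'   [generate_benchmark()] result.
#' @param methods named list of fitted [stdta_har()] models (any mix of
#'   `method = "stdta"` and `method = "flat"`).
#' @return List of class `"har_report"`: per-method `confusion` and `recall`,
#'   plus `n_windows`.
#' @export
compare_methods <- function(streams, methods) {
  if (inherits(streams, "har_benchmark")) streams <- streams$streams
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  if (!length(methods) || is.null(names(methods))) {
    stop("methods must be a named list of fitted models")
  }
  lv <- activity_levels(transition = TRUE)
  truth <- unlist(lapply(streams, function(s) {
    tl <- sliding_windows(s)$truth
    if (is.null(tl)) stop("streams must carry ground-truth labels")
    tl
  }))
  out <- lapply(methods, function(m) {
    pred <- unlist(lapply(streams, function(s) predict(m, s)$label))
    cm <- confusion_matrix(truth, pred, levels = lv)
    list(confusion = cm, recall = recall_per_class(cm))
  })
  structure(list(methods = out, n_windows = length(truth)),
            class = "har_report")
}

#' @export
print.har_report <- function(x, ...) {
  cat(sprintf("<har_report> %d windows, %d method(s)\n",
              x$n_windows, length(x$methods)))
  for (nm in names(x$methods)) {
    cat("\n==", nm, "==\n")
    print(x$methods[[nm]]$confusion)
  }
  invisible(x)
}
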