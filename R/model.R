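#' Fit a transition-aware activity recognition model
#'
#' The main fitting function of the package. From labelled training streams
#' it extracts overlapping windows (1 s, 0.5 s stride by default), computes
#' the 63 per-window statistical features, and trains the probabilistic
#' basic-activity classifier. Two methods are available:
#'
#' * `method = "stdta"` (default): the classifier is trained on the eight
#'   basic activities only; at prediction time the STD-TA state machine
#'   watches the trend of the windowed standard deviation of `acc_all` and
#'   overrides the classifier with the `"Transition"` label while a
#'   transition is in progress.
#' * `method = "flat"`: the baseline that treats all transitions as a ninth
#'   activity class and leaves everything to the classifier.
#'
#' With `fit_gate = TRUE` the model additionally computes the four gate
#' factors on every training window (in-sample probabilities) and solves the
#' no-intercept least-squares problem `theta %*% W ~ 1{transition}`; the raw
#' coefficients are stored for inspection (`coef(fit)`), while the runtime
#' gate keeps the `weights` supplied — translating raw least-squares weights
#' into runtime gate weights is a documented manual fine-tuning step.
#'
#' @param streams a labelled [sensor_stream()] or a list of them; a
#'   [generate_training_streams()] result is also accepted (all its streams
#'   are used).
#' @param method `"stdta"` or `"flat"`.
#' @param window,step window size and stride in frames.
#' @param classifier backend passed to [train_classifier()].
#' @param weights runtime [gate_weights()].
#' @param fit_gate also estimate raw gate weights by least squares.
#' @param enforce_diagram restrict post-transition labels to
#'   diagram-adjacent activities at prediction time.
#' @param seed integer seed for the classifier backend.
#' @param ... passed to [train_classifier()].
#' @return An object of class `"stdta_har"`.
#' @seealso [predict.stdta_har()], [compare_methods()], [generate_benchmark()]
#' @export
#' @examples
#' \donttest{
#' tr <- generate_training_streams(seed = 1, basic_points = 1500,
#'                                 stairs_points = 1500, pair_points = 2000)
#' fit <- stdta_har(tr, seed = 1)
#' bench <- generate_benchmark(2, seed = 2, total_points = 3000)
#' timeline <- predict(fit, bench$streams[[1]])
#' table(timeline$label)
#' }
stdta_har <- function(streams, method = c("stdta", "flat"), window = 50L,
                      step = 25L, classifier = "svm",
                      weights = gate_weights(), fit_gate = FALSE,
                      enforce_diagram = FALSE, seed = 1L, ...) {
  method <- match.arg(method)
  if (is.list(streams) && !inherits(streams, "sensor_stream") &&
      all(c("pure", "pairs") %in% names(streams))) {
    streams <- c(streams$pure, streams$pairs)
  }
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  fms <- lapply(streams, feature_matrix, size = window, step = step)
  truths <- lapply(fms, attr, "truth")
  if (any(vapply(truths, is.null, TRUE))) {
    stop("training streams must carry per-frame activity labels")
  }
  x <- do.call(rbind, fms)
  y <- unlist(truths)
  basic <- y != "Transition"
  if (method == "flat") {
    if (!any(!basic)) stop("flat method needs transition windows for training")
    clf <- train_classifier(x, y, model = classifier, seed = seed,
                            levels = activity_levels(TRUE), ...)
  } else {
    clf <- train_classifier(x[basic, , drop = FALSE], y[basic],
                            model = classifier, seed = seed,
                            levels = activity_levels(), ...)
  }
  raw_w <- NULL
  if (fit_gate && method == "stdta") {
    th <- do.call(rbind, lapply(fms, function(fm) {
      training_theta(clf, fm, weights)
    }))
    raw_w <- fit_gate_weights(th[, 1:4, drop = FALSE], th[, 5])
  }
  structure(list(method = method, classifier = clf, weights = weights,
                 raw_weights = raw_w, window = as.integer(window),
                 step = as.integer(step), enforce_diagram = enforce_diagram,
                 diagram = transition_diagram(), call = match.call()),
            class = "stdta_har")
}

# theta rows + 0/1 transition label for gate-weight estimation on a labelled
# feature matrix (in-sample probabilities).
training_theta <- function(clf, fm, weights) {
  probs <- predict(clf, fm, type = "prob")
  stds <- std_series(fm)
  n <- nrow(fm)
  d <- if (n >= 2) diff(stds) else numeric(0)
  dd <- function(j) if (j >= 1 && j <= length(d)) d[j] else 0
  th <- t(vapply(seq_len(n), function(i) {
    compute_theta(dd(i - 2L), dd(i - 1L), dd(i), max(probs[i, ]),
                  weights$diff_threshold)
  }, numeric(4)))
  cbind(th, trans = as.numeric(attr(fm, "truth") == "Transition"))
}

#' @export
print.stdta_har <- function(x, ...) {
  cat(sprintf("<stdta_har> method=%s, classifier=%s, window=%d/%d\n",
              x$method, x$classifier$model, x$window, x$step))
  cat("  classes:", paste(x$classifier$levels, collapse = ", "), "\n")
  if (x$method == "stdta") print(x$weights)
  if (!is.null(x$raw_weights)) {
    cat("  raw least-squares gate weights:",
        paste(sprintf("%.6f", x$raw_weights), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.stdta_har <- function(object, ...) {
  print(object)
  cat("  feature schema:", length(object$classifier$schema), "features\n")
  invisible(object)
}

#' Gate weights of a fitted model
#'
#' Returns the runtime gate weights `(w1, w2, w3, w4)`; when the model was
#' fitted with `fit_gate = TRUE`, the raw least-squares coefficients are
#' attached as attribute `"raw"`.
#'
#' @param object a fitted [stdta_har()] model.
#' @param ... unused.
#' @export
coef.stdta_har <- function(object, ...) {
  w <- object$weights
  out <- c(w1 = w$w1, w2 = w$w2, w3 = w$w3, w4 = w$w4)
  if (!is.null(object$raw_weights)) attr(out, "raw") <- object$raw_weights
  out
}

#' Run the recognition pipeline over a stream
#'
#' Segments the stream, extracts features, obtains the probabilistic result
#' of every window and — for `method = "stdta"` models — drives the STD-TA
#' state machine over the window sequence to flag transitions.
#'
#' @param object a fitted [stdta_har()] model.
#' @param newdata a [sensor_stream()], or a per-window feature matrix from
#'   [feature_matrix()].
#' @param type `"timeline"` (default) for the per-window label timeline,
#'   `"prob"` for the classifier probability matrix.
#' @param prev_label label assumed before the first window (default: first
#'   window's classifier argmax).
#' @param ... unused.
#' @return For `type = "timeline"`, an `"stdta_timeline"` data.frame with
#'   columns `window_start`, `label`, `maxp`, `std`, `intrans`, `count`, `r`,
#'   `trans_before`, `trans_after` and, when the stream is labelled, `truth`.
#' @export
predict.stdta_har <- function(object, newdata, type = c("timeline", "prob"),
                              prev_label = NULL, ...) {
  type <- match.arg(type)
  fm <- if (inherits(newdata, "sensor_stream")) {
    feature_matrix(newdata, size = object$window, step = object$step)
  } else newdata
  probs <- predict(object$classifier, fm, type = "prob")
  if (type == "prob") return(probs)
  stds <- std_series(fm)
  if (object$method == "stdta") {
    tl <- run_stdta(probs, stds, prev_label = prev_label,
                    weights = object$weights,
                    enforce_diagram = object$enforce_diagram,
                    diagram = object$diagram)
  } else {
    tl <- data.frame(label = argmax_label(probs), maxp = apply(probs, 1, max),
                     std = stds, intrans = NA, count = NA_integer_,
                     r = NA_real_, trans_before = NA_character_,
                     trans_after = NA_character_)
    class(tl) <- c("stdta_timeline", "data.frame")
  }
  tl <- cbind(window_start = attr(fm, "window_start"), tl)
  if (!is.null(attr(fm, "truth"))) tl$truth <- attr(fm, "truth")
  if (!is.null(attr(fm, "segment"))) tl$segment <- attr(fm, "segment")
  class(tl) <- c("stdta_timeline", "data.frame")
  tl
}

#' Plot a recognition timeline
#'
#' Draws the window STD series with the static entry/exit threshold and
#' shades the windows labelled as transitions — the standard diagnostic view
#' of the trend detector.
#'
#' @param x an `"stdta_timeline"` from [predict.stdta_har()].
#' @param ... passed to [plot()].
#' @export
plot.stdta_timeline <- function(x, ...) {
  i <- seq_len(nrow(x))
  graphics::plot(i, x$std, type = "l", xlab = "window",
                 ylab = "STD of acc_all (m/s^2)", ...)
  trans <- x$label == "Transition"
  if (any(trans)) {
    graphics::rect(i[trans] - 0.5, graphics::par("usr")[3], i[trans] + 0.5,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("tomato", 0.25), border = NA)
  }
  graphics::abline(h = 0.1, lty = 2, col = "grey40")
  invisible(x)
}

#' Simulate benchmark sequences from a fitted model's conditions
#'
#' Delegates to [generate_benchmark()] with the generator defaults, giving
#' `nsim` labelled sequences suitable for evaluating the fitted model.
#'
#' @param object a fitted [stdta_har()] model (window configuration is
#'   reused).
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param ... passed to [generate_benchmark()].
#' @return A `"har_benchmark"` list (streams + manifest).
#' @export
simulate.stdta_har <- function(object, nsim = 1L, seed = 1L, ...) {
  generate_benchmark(n_sequences = nsim, seed = seed, ...)
}
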