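#' Transition-gate weights and thresholds
#'
#' Bundles every tunable constant of the STD-TA state machine:
#'
#' * `w1, w2, w3`: weights of the historical-trend, future-trend and
#'   change-magnitude indicators in the gate score;
#' * `w4`: magnitude of the confidence penalty — the score subtracts
#'   `(1 - theta4) * w4`;
#' * `r_threshold`: the gate fires when the score reaches this value
#'   (default 1.22);
#' * `std_enter`: windowed STD (m/s^2) above which a window following a
#'   static activity can enter a transition, and at or below which any
#'   ongoing transition ends (default 0.1);
#' * `maxp_exit`: classifier confidence at or above which an ongoing
#'   transition ends, and below which a post-static window can enter one
#'   (default 0.9);
#' * `diff_threshold`: absolute STD difference that counts as a huge
#'   real-time change, the theta3 indicator (default 0.1);
#' * `count_max`: maximum number of consecutive windows a transition may
#'   last before it is cut off (default 7, about 3.5 s at a 25-frame stride —
#'   the longest observed transition, sit-to-stand at 150--160 frames, spans
#'   roughly 6.4 windows).
#'
#' @param w1,w2,w3,w4 gate weights (defaults 0.5, 0.4, 0.35, 0.625).
#' @param r_threshold,std_enter,maxp_exit,diff_threshold,count_max see above.
#' @return A list of class `"gate_weights"`.
#' @export
gate_weights <- function(w1 = 0.5, w2 = 0.4, w3 = 0.35, w4 = 0.625,
                         r_threshold = 1.22, std_enter = 0.1,
                         maxp_exit = 0.9, diff_threshold = 0.1,
                         count_max = 7L) {
  stopifnot(r_threshold > 0, std_enter > 0, count_max >= 1)
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4,
                 r_threshold = r_threshold, std_enter = std_enter,
                 maxp_exit = maxp_exit, diff_threshold = diff_threshold,
                 count_max = as.integer(count_max)),
            class = "gate_weights")
}

#' @export
print.gate_weights <- function(x, ...) {
  cat(sprintf(paste0("STD-TA gate: R = %.3g*t1 + %.3g*t2 + %.3g*t3 - ",
                     "(1-t4)*%.3g, fire at R >= %.3g\n"),
              x$w1, x$w2, x$w3, x$w4, x$r_threshold))
  cat(sprintf("  std_enter %.3g, maxp_exit %.3g, diff_threshold %.3g, count_max %d\n",
              x$std_enter, x$maxp_exit, x$diff_threshold, x$count_max))
  invisible(x)
}

#' First differences of the window STD series
#'
#' `diff_series(stds)[j] = stds[j+1] - stds[j]` — the raw trend signal of the
#' transition detector.
#'
#' @param stds numeric STD series, length >= 2.
#' @return Numeric vector one shorter than the input.
#' @export
#' @examples
#' diff_series(c(0.1, 0.3, 0.2))  # 0.2 -0.1
diff_series <- function(stds) {
  if (length(stds) < 2L) stop("need at least 2 STD values")
  diff(stds)
}

#' The four transition-gate factors
#'
#' For window `i` with STD differences `diff_prev = STD[i-1] - STD[i-2]`,
#' `diff_cur = STD[i] - STD[i-1]` and `diff_next = STD[i+1] - STD[i]`:
#'
#' * `theta1` (historical trend) is 1 when `diff_cur * diff_prev > 0`, i.e.
#'   the last three STD values move in the same direction;
#' * `theta2` (future trend) is 1 when `diff_next * diff_cur > 0`;
#' * `theta3` (real-time change) is 1 when `|diff_cur|` exceeds
#'   `diff_threshold`;
#' * `theta4` (classifier confidence) is `max(P_i)` floored at 0.6.
#'
#' Differences unavailable at the sequence boundary should be passed as 0,
#' which switches the corresponding indicator off.
#'
#' @param diff_prev,diff_cur,diff_next STD differences (see above).
#' @param maxp maximum basic-class probability of the current window, in
#'   `[0, 1]`.
#' @param diff_threshold change-magnitude threshold (default 0.1).
#' @return Named numeric vector `(theta1, theta2, theta3, theta4)`.
#' @export
#' @examples
#' compute_theta(0.2, 0.15, 0.12, maxp = 0.95)  # 1 1 1 0.95
compute_theta <- function(diff_prev, diff_cur, diff_next, maxp,
                          diff_threshold = 0.1) {
  stopifnot(maxp >= 0, maxp <= 1)
  c(theta1 = as.numeric(diff_cur * diff_prev > 0),
    theta2 = as.numeric(diff_next * diff_cur > 0),
    theta3 = as.numeric(abs(diff_cur) > diff_threshold),
    theta4 = if (maxp < 0.6) 0.6 else maxp)
}

#' Transition-gate score
#'
#' `R = w1*theta1 + w2*theta2 + w3*theta3 - (1 - theta4)*w4`. With the default
#' weights, R ranges over `[-0.25, 1.25]` and reaches the firing threshold
#' 1.22 only when all three trend indicators are 1 and the classifier
#' confidence factor theta4 is at least 0.952.
#'
#' @param theta factor vector from [compute_theta()].
#' @param weights a [gate_weights()] object.
#' @return The scalar gate score R.
#' @export
#' @examples
#' gate_score(compute_theta(0.2, 0.15, 0.12, maxp = 1))  # 1.25
gate_score <- function(theta, weights = gate_weights()) {
  unname(weights$w1 * theta[["theta1"]] + weights$w2 * theta[["theta2"]] +
         weights$w3 * theta[["theta3"]] -
         (1 - theta[["theta4"]]) * abs(weights$w4))
}

#' Initial state of the STD-TA machine
#'
#' @param prev_label activity label assumed for the window before the first
#'   one (its class decides which entry rule the first window uses).
#' @return A list of class `"transition_state"` with fields `intrans`
#'   (in-transition flag), `count` (windows spent in the ongoing transition;
#'   0 whenever `intrans` is FALSE) and `prev_label`.
#' @export
transition_state <- function(prev_label = "Standing") {
  structure(list(intrans = FALSE, count = 0L, prev_label = prev_label),
            class = "transition_state")
}

#' One step of the STD-TA state machine
#'
#' Decides the label of the current window from the previous window's label,
#' the STD trend around the current window, and the classifier's probabilistic
#' result. The rules:
#'
#' 1. **Exit check** (only for a transition carried in from previous windows):
#'    the transition ends when the window STD falls to `std_enter` or below,
#'    or the classifier is confident (`maxp >= maxp_exit`), or the transition
#'    has already lasted `count_max` windows.
#' 2. **Entry check** (when not in a transition after step 1): after a static
#'    activity, a transition starts when `std > std_enter` and
#'    `maxp < maxp_exit`; after a dynamic activity or an ongoing transition
#'    that just ended, the four theta factors are combined into the gate score
#'    R and a transition starts when `R >= r_threshold`.
#' 3. The window is labelled `"Transition"` while in a transition, otherwise
#'    with the classifier argmax.
#'
#' @param state a [transition_state()].
#' @param std_i window STD of `acc_all`.
#' @param diff_prev,diff_cur,diff_next STD differences around the window
#'   (pass 0 where unavailable at a boundary).
#' @param prob probability vector over the basic activities (named, summing
#'   to 1), or a 1-row matrix.
#' @param weights a [gate_weights()] object.
#' @return List with `label` (the emitted activity label), `state` (the
#'   updated [transition_state()]), and the diagnostic scalars `theta`
#'   (factor vector or NULL on the static branch) and `r` (gate score or NA).
#' @export
stdta_step <- function(state, std_i, diff_prev, diff_cur, diff_next, prob,
                       weights = gate_weights()) {
  p <- as.numeric(prob)
  names(p) <- if (is.matrix(prob)) colnames(prob) else names(prob)
  maxp <- max(p)
  best <- names(p)[which.max(p)]
  intrans <- state$intrans
  count <- state$count
  # 1. exit check on an ongoing transition
  if (intrans && (std_i <= weights$std_enter || maxp >= weights$maxp_exit ||
                  count >= weights$count_max)) {
    intrans <- FALSE
    count <- 0L
  }
  theta <- NULL; r <- NA_real_
  if (!intrans) {
    # 2. entry check
    prev_static <- !is.null(state$prev_label) &&
      activity_class(state$prev_label) == "static"
    if (prev_static) {
      if (std_i > weights$std_enter && maxp < weights$maxp_exit) intrans <- TRUE
    } else {
      theta <- compute_theta(diff_prev, diff_cur, diff_next, maxp,
                             weights$diff_threshold)
      r <- gate_score(theta, weights)
      if (r >= weights$r_threshold) intrans <- TRUE
    }
    if (intrans) count <- 1L
  } else {
    count <- count + 1L
  }
  label <- if (intrans) "Transition" else best
  list(label = label,
       state = structure(list(intrans = intrans, count = count,
                              prev_label = label),
                         class = "transition_state"),
       theta = theta, r = r)
}

#' Run STD-TA over a window sequence
#'
#' Drives [stdta_step()] across a whole sequence of windows. Window `i` uses
#' `diff_next = STD[i+1] - STD[i]`, so in a streaming setting its label is
#' available one window late; differences that do not exist at the boundaries
#' are taken as 0 (first window: no trend factors; last window: no future
#' trend).
#'
#' When `enforce_diagram = TRUE`, the basic label emitted right after each
#' window is restricted to activities reachable from the last confirmed basic
#' activity in the transition diagram (the last basic activity itself and its
#' neighbours); the highest-probability activity in that set is chosen.
#'
#' @param probs probability matrix from [predict.har_classifier()], one row
#'   per window, columns = basic activities.
#' @param stds window STD series of `acc_all`, same length as `nrow(probs)`.
#' @param prev_label label assumed before the first window; default is the
#'   first window's classifier argmax.
#' @param weights a [gate_weights()] object.
#' @param enforce_diagram restrict post-transition labels to
#'   diagram-plausible activities (default FALSE).
#' @param diagram a [transition_diagram()] (used when `enforce_diagram`).
#' @return A data.frame of class `"stdta_timeline"` with one row per window:
#'   `label`, `maxp`, `std`, `intrans`, `count`, `r`, and — for windows inside
#'   a transition run — `trans_before`/`trans_after`, the flanking basic
#'   labels that identify which of the 14 transition types occurred.
#' @export
run_stdta <- function(probs, stds, prev_label = NULL,
                      weights = gate_weights(), enforce_diagram = FALSE,
                      diagram = transition_diagram()) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  if (length(stds) != n) stop("probs and stds lengths differ")
  if (n == 0L) stop("empty window sequence")
  if (is.null(prev_label)) prev_label <- argmax_label(probs[1, , drop = FALSE])
  d <- if (n >= 2) diff(stds) else numeric(0)  # d[j] = STD[j+1] - STD[j]
  dd <- function(j) if (j >= 1 && j <= length(d)) d[j] else 0
  state <- transition_state(prev_label)
  label <- character(n); intrans <- logical(n); count <- integer(n)
  rv <- rep(NA_real_, n); maxp <- numeric(n)
  last_basic <- if (activity_class(prev_label) != "transition") prev_label else NULL
  for (i in seq_len(n)) {
    res <- stdta_step(state, stds[i],
                      diff_prev = dd(i - 2L), diff_cur = dd(i - 1L),
                      diff_next = dd(i), probs[i, , drop = FALSE], weights)
    lab <- res$label
    if (enforce_diagram && lab != "Transition" && !is.null(last_basic) &&
        lab != last_basic && !diagram[last_basic, lab]) {
      allowed <- c(last_basic, colnames(probs)[diagram[last_basic, colnames(probs)]])
      sub <- probs[i, allowed, drop = FALSE]
      lab <- allowed[which.max(sub)]
      res$state$prev_label <- lab
    }
    label[i] <- lab
    if (lab != "Transition") last_basic <- lab
    state <- res$state
    intrans[i] <- state$intrans; count[i] <- state$count
    rv[i] <- res$r; maxp[i] <- max(probs[i, ])
  }
  out <- data.frame(label = label, maxp = maxp, std = stds,
                    intrans = intrans, count = count, r = rv)
  spans <- transition_spans(label)
  out$trans_before <- NA_character_; out$trans_after <- NA_character_
  for (k in seq_len(nrow(spans))) {
    idx <- spans$from[k]:spans$to[k]
    out$trans_before[idx] <- spans$before[k]
    out$trans_after[idx] <- spans$after[k]
  }
  class(out) <- c("stdta_timeline", "data.frame")
  out
}

# Maximal runs of "Transition" labels with their flanking basic activities
# (NA at sequence edges) — the basis for inferring the transition sub-type.
transition_spans <- function(labels) {
  r <- rle(labels == "Transition")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(from = starts[keep], to = ends[keep],
             before = ifelse(starts[keep] > 1L, labels[starts[keep] - 1L], NA),
             after = ifelse(ends[keep] < length(labels), labels[ends[keep] + 1L], NA))
}

#' Fit raw gate weights by least squares
#'
#' Solves `theta %*% W ~ y` in the least-squares sense with no intercept,
#' where each row of `theta` holds the four gate factors of a labelled window
#' and `y` is 0 for a basic-activity window and 1 for a transition window
#' (multiple linear regression through the origin). The returned raw
#' coefficients are reported as fitted; mapping them onto runtime
#' [gate_weights()] (w1..w3 directly, `|W4|` as the confidence-penalty
#' magnitude) is a deliberate manual fine-tuning step, because the runtime
#' score uses the algebraically different form `-(1 - theta4) * w4`.
#'
#' @param theta numeric n x 4 matrix of gate factors, n >= 4, full rank.
#' @param y numeric 0/1 labels, one per row.
#' @return Numeric vector `(W1, W2, W3, W4)` of raw least-squares
#'   coefficients.
#' @export
fit_gate_weights <- function(theta, y) {
  theta <- as.matrix(theta)
  if (ncol(theta) != 4L) stop("theta must have 4 columns")
  if (nrow(theta) < 4L) stop("need at least 4 rows")
  if (length(y) != nrow(theta)) stop("theta and y lengths differ")
  if (qr(theta)$rank < 4L) {
    stop("theta design is rank-deficient; the four factors must vary independently")
  }
  fit <- stats::lm.fit(theta, as.numeric(y))
  w <- unname(fit$coefficients)
  names(w) <- c("W1", "W2", "W3", "W4")
  w
}
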