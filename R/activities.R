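#' Basic activity labels
#'
#' The eight basic activities recognised by the pipeline, in their canonical
#' order (A01--A08): Sitting, Standing, Lying, Walking, Upstairs, Downstairs,
#' Running, QuickWalk. The ninth label, `"Transition"`, marks the transitional
#' process between two basic activities and is emitted by the STD-TA state
#' machine rather than the basic classifier.
#'
#' @param transition logical; append the `"Transition"` label as ninth class.
#' @return Character vector of activity labels in canonical order.
#' @seealso [activity_class()], [transition_diagram()]
#' @export
#' @examples
#' activity_levels()
#' activity_levels(transition = TRUE)
activity_levels <- function(transition = FALSE) {
  base <- c("Sitting", "Standing", "Lying", "Walking", "Upstairs",
            "Downstairs", "Running", "QuickWalk")
  if (transition) c(base, "Transition") else base
}

#' Activity category (static / dynamic / transition)
#'
#' Sitting, Standing and Lying are long-term stable postures (static
#' activities); Walking, Upstairs, Downstairs, Running and QuickWalk are
#' locomotion modes (dynamic activities).
#'
#' @param label character vector of activity labels.
#' @return Character vector with entries `"static"`, `"dynamic"` or
#'   `"transition"`.
#' @export
#' @examples
#' activity_class(c("Sitting", "Running", "Transition"))
activity_class <- function(label) {
  static <- c("Sitting", "Standing", "Lying")
  dynamic <- c("Walking", "Upstairs", "Downstairs", "Running", "QuickWalk")
  out <- rep(NA_character_, length(label))
  out[label %in% static] <- "static"
  out[label %in% dynamic] <- "dynamic"
  out[label == "Transition"] <- "transition"
  if (anyNA(out)) {
    stop("unknown activity label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  }
  out
}

#' Transition diagram over the basic activities
#'
#' The undirected adjacency over the eight basic activities that defines which
#' transitions are physically plausible. The default diagram has seven edges
#' (fourteen directed transitions): Lying--Standing, Sitting--Standing,
#' Standing--Upstairs, Standing--Downstairs, Standing--Walking,
#' Walking--Running and Walking--QuickWalk. Pairs without an edge, such as
#' Lying and Running, cannot transition directly.
#'
#' @param pairs two-column character matrix (or data.frame) of undirected
#'   edges; defaults to the seven canonical pairs.
#' @return An object of class `"transition_diagram"`: a symmetric logical
#'   adjacency matrix over [activity_levels()].
#' @export
#' @examples
#' d <- transition_diagram()
#' sum(d)  # 14 directed transitions
transition_diagram <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- rbind(
      c("Lying",    "Standing"),
      c("Sitting",  "Standing"),
      c("Standing", "Upstairs"),
      c("Standing", "Downstairs"),
      c("Standing", "Walking"),
      c("Walking",  "Running"),
      c("Walking",  "QuickWalk"))
  }
  pairs <- as.matrix(pairs)
  lv <- activity_levels()
  bad <- setdiff(unique(c(pairs)), lv)
  if (length(bad)) stop("unknown activity in diagram: ", paste(bad, collapse = ", "))
  adj <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (k in seq_len(nrow(pairs))) {
    adj[pairs[k, 1], pairs[k, 2]] <- TRUE
    adj[pairs[k, 2], pairs[k, 1]] <- TRUE
  }
  structure(adj, class = c("transition_diagram", "matrix"))
}

#' Is a direct transition between two basic activities allowed?
#'
#' @param a,b distinct basic activity labels.
#' @param diagram a [transition_diagram()].
#' @return `TRUE` if `a` and `b` are adjacent in the diagram.
#' @export
#' @examples
#' transition_allowed("Lying", "Standing")  # TRUE
#' transition_allowed("Lying", "Running")   # FALSE
transition_allowed <- function(a, b, diagram = transition_diagram()) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (a == b) stop("a transition requires two distinct basic activities")
  unname(diagram[a, b])
}
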