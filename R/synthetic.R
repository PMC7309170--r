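#' Default motion regimes for the synthetic generator
#'
#' One regime per basic activity, parameterising the synthetic signal model:
#' a gravity vector of fixed posture-dependent orientation, a sinusoidal
#' oscillation of given amplitude and frequency shared by the three axes with
#' phase offsets, additive Gaussian noise, and a barometric baseline with a
#' per-regime drift (stairs only: climbing lowers pressure, descending raises
#' it).
#'
#' The numeric defaults are calibration choices of this package, anchored to
#' the value ranges a leg-worn smartphone produces: static window STD of
#' `acc_all` around 0.016 m/s^2 (well under the 0.1 static threshold), dynamic
#' window STDs within (0.1, 2.2], window means of `acc_all` within 9--13
#' m/s^2, and a stair pressure drift of 0.04 hPa/s. They are not measurements
#' of any real subject.
#'
#' @return A data.frame of class `"regime_table"`, one row per basic
#'   activity: `activity`, `acc_amplitude` (m/s^2), `acc_frequency` (Hz),
#'   `acc_noise_sd` (m/s^2), `baro_drift` (hPa/s), `baro_noise_sd` (hPa) and
#'   the gravity orientation `orient_x, orient_y, orient_z` (unit vector).
#' @export
default_regimes <- function() {
  df <- data.frame(
    activity      = activity_levels(),
    acc_amplitude = c(0,     0,     0,     0.8,  1.0,   1.0,  2.5, 1.8),
    acc_frequency = c(0,     0,     0,     1.8,  1.5,   1.6,  3.0, 2.2),
    acc_noise_sd  = c(0.016, 0.016, 0.016, 0.10, 0.10,  0.10, 0.15, 0.12),
    baro_drift    = c(0,     0,     0,     0,    -0.04, 0.04, 0,   0),
    baro_noise_sd = 0.02,
    orient_x      = c(1, 0, 0, 0, 0, 0, 0, 0),
    orient_y      = c(0, 0, 1, 0, 0, 0, 0, 0),
    orient_z      = c(0, 1, 0, 1, 1, 1, 1, 1))
  class(df) <- c("regime_table", "data.frame")
  df
}

#' Default transition durations (frames at 50 Hz)
#'
#' Typical durations of the seven plausible transitions, in data points.
#' Postural transitions are slow (about 3 s), gait-change transitions fast
#' (well under a second). The Lying--Standing duration is set equal to the
#' other postural transition, Sitting--Standing.
#'
#' @return Named integer vector keyed by `"A|B"` with the pair in canonical
#'   activity order.
#' @export
default_transition_durations <- function() {
  c("Standing|Lying"       = 150L,
    "Sitting|Standing"     = 150L,
    "Standing|Upstairs"    = 40L,
    "Standing|Downstairs"  = 50L,
    "Standing|Walking"     = 45L,
    "Walking|Running"      = 15L,
    "Walking|QuickWalk"    = 15L)
}

#' Draw subject-level signal parameters
#'
#' Emulates between-subject variation in a multi-subject collection: an
#' overall gait intensity scale, a cadence scale, a device-mounting tilt
#' (rotation of the gravity orientation in the sagittal plane) and a sensor
#' noise scale. Drawn from the current RNG state.
#'
#' @param gait_sd,cadence_sd relative standard deviations of the intensity
#'   and cadence scales.
#' @param tilt_sd mounting tilt standard deviation, degrees.
#' @return List with `gait_scale`, `cadence_scale`, `tilt_deg`,
#'   `noise_scale`.
#' @export
sample_subject <- function(gait_sd = 0.15, cadence_sd = 0.08, tilt_sd = 6) {
  list(gait_scale = min(1.4, max(0.6, stats::rnorm(1, 1, gait_sd))),
       cadence_scale = min(1.25, max(0.75, stats::rnorm(1, 1, cadence_sd))),
       tilt_deg = stats::rnorm(1, 0, tilt_sd),
       noise_scale = stats::runif(1, 0.8, 1.3))
}

default_subject <- function() {
  list(gait_scale = 1, cadence_scale = 1, tilt_deg = 0, noise_scale = 1)
}

# Canonical "A|B" key for an unordered activity pair.
pair_key <- function(a, b) {
  lv <- activity_levels()
  i <- match(c(a, b), lv)
  if (anyNA(i)) stop("unknown activity: ", paste(c(a, b)[is.na(i)], collapse = ", "))
  paste(lv[sort(i)], collapse = "|")
}

#' Build a basic/transition schedule
#'
#' Expands a sequence of basic activities into the alternating
#' basic--transition--basic pattern, inserting one transition item between
#' each pair of consecutive distinct activities with the pair's default
#' duration.
#'
#' @param activities character vector of basic activities; consecutive
#'   entries must be distinct, diagram-adjacent pairs.
#' @param basic_duration frames per basic segment (one value or one per
#'   activity).
#' @param durations named transition-duration vector as from
#'   [default_transition_durations()].
#' @return Schedule data.frame with columns `activity` (label or
#'   `"Transition"`), `duration`, `from`, `to`.
#' @export
#' @examples
#' schedule_pattern(c("Standing", "Walking", "Standing"), 500)
schedule_pattern <- function(activities, basic_duration,
                             durations = default_transition_durations()) {
  stopifnot(length(activities) >= 1)
  basic_duration <- rep_len(as.integer(basic_duration), length(activities))
  rows <- list()
  for (i in seq_along(activities)) {
    rows[[length(rows) + 1L]] <- data.frame(
      activity = activities[i], duration = basic_duration[i],
      from = NA_character_, to = NA_character_)
    if (i < length(activities)) {
      a <- activities[i]; b <- activities[i + 1L]
      if (a == b) stop("consecutive activities must differ")
      key <- pair_key(a, b)
      if (!key %in% names(durations)) stop("no duration for transition ", key)
      rows[[length(rows) + 1L]] <- data.frame(
        activity = "Transition", duration = as.integer(durations[[key]]),
        from = a, to = b)
    }
  }
  do.call(rbind, rows)
}

#' Generate a labelled synthetic sensor stream
#'
#' Synthesises a 50 Hz accelerometer + barometer stream following a schedule
#' of basic-activity segments and transition segments. Within a basic
#' segment each axis carries `amplitude * sin(2*pi*f*t + phase_axis)` (axis
#' phases 0, 2pi/3, 4pi/3) on top of the posture's gravity component, plus
#' white Gaussian noise; the barometer integrates the regime drift, is
#' sampled at 5 Hz with its own noise, and is aligned to the 50 Hz grid by
#' sample-and-hold. Transition segments cross-fade the regime parameters
#' between the flanking regimes, which produces the multi-window ramp in
#' windowed STD that the trend detector keys on.
#'
#' On top of the cross-fade, the generator reproduces the signal features
#' that make real transitions both intense and ambiguous to a per-window
#' classifier: an irregular movement-initiation burst when leaving a rest
#' posture (persisting into the first unsteady strides), terminal weight-
#' settling sway up to the labelled end of a transition into rest, a
#' postural-adjustment tilt of the gravity orientation that leads/trails the
#' labelled boundaries, anticipatory deceleration (to 0.4 of nominal
#' amplitude over ~1.5 s) before stopping and the mirrored warm-up after
#' starting, per-event execution heterogeneity, stride-to-stride gait
#' variability, and sparse sub-threshold fidgets within rest postures.
#' The oscillator phase is continuous across segments. Per-frame truth
#' labels and segment ids are attached; output is deterministic given
#' `seed`.
#'
#' @param schedule data.frame as from [schedule_pattern()] (columns
#'   `activity`, `duration`, and `from`/`to` for transition rows).
#' @param regimes a [default_regimes()] table.
#' @param seed integer RNG seed.
#' @param fs accelerometer sampling rate, Hz.
#' @param baro_factor accelerometer frames per barometer sample.
#' @param baro_base baseline pressure, hPa.
#' @param gravity gravitational acceleration, m/s^2.
#' @param gait_variability relative sd of the slow stride-to-stride
#'   amplitude modulation.
#' @param burst_amplitude peak movement-initiation burst, m/s^2.
#' @param subject subject-level parameters from [sample_subject()]; `NULL`
#'   for the nominal subject.
#' @return A labelled [sensor_stream()].
#' @export
generate_stream <- function(schedule, regimes = default_regimes(), seed = 1L,
                            fs = 50, baro_factor = 10L, baro_base = 1013.25,
                            gravity = 9.81, gait_variability = 0.10,
                            burst_amplitude = 0.8, subject = NULL) {
  stopifnot(nrow(schedule) >= 1)
  set.seed(seed)
  if (is.null(subject)) subject <- default_subject()
  regimes <- apply_subject(regimes, subject)
  par_cols <- c("acc_amplitude", "acc_frequency", "acc_noise_sd",
                "baro_drift", "baro_noise_sd", "orient_x", "orient_y",
                "orient_z")
  regime_row <- function(act) {
    i <- match(act, regimes$activity)
    if (is.na(i)) stop("activity not in regime table: ", act)
    unlist(regimes[i, par_cols])
  }
  par <- matrix(NA_real_, 0, length(par_cols),
                dimnames = list(NULL, par_cols))
  label <- character(0); segment <- integer(0)
  burst <- numeric(0); wobble <- numeric(0)
  wsc <- rep(NA_real_, nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    dur <- schedule$duration[k]
    if (schedule$activity[k] == "Transition") {
      from <- regime_row(schedule$from[k]); to <- regime_row(schedule$to[k])
      alpha <- seq_len(dur) / (dur + 1)
      block <- outer(1 - alpha, from) + outer(alpha, to)
      colnames(block) <- par_cols
      # postural adjustment: the leg tilts while weight shifts — early in
      # the transition when initiating movement from rest, late when
      # coming to rest from locomotion
      cls_from <- activity_class(schedule$from[k])
      cls_to <- activity_class(schedule$to[k])
      if (cls_from == "dynamic" && cls_to == "static") {
        # stopping: the stride amplitude continues the anticipatory taper
        # (0.4 of nominal at the boundary) and drops mostly over the first
        # part of the transition, then the body settles
        block[, "acc_amplitude"] <-
          0.4 * from[["acc_amplitude"]] * (1 - alpha)^1.5
      } else if (cls_from == "static" && cls_to == "dynamic") {
        # gait builds up toward the warm-up level (0.4 of nominal) that the
        # following segment starts from
        block[, "acc_amplitude"] <- 0.4 * to[["acc_amplitude"]] * alpha
      }
      # executions vary from one occurrence to the next
      bscale <- stats::runif(1, 0.85, 1.35)
      wscale <- stats::runif(1, 0.85, 1.35)
      wsc[k] <- wscale
      # mixed static/dynamic transitions get their tilt hump in the
      # post-loop pass below (it extends beyond the labelled segment);
      # between two postures the in-segment tilt is symmetric
      w <- wscale * if (cls_from == "static" && cls_to == "static") {
        sin(pi * alpha)
      } else rep(0, dur)
      # movement initiation from rest is a ballistic, irregular burst;
      # terminating an ongoing gait is a smooth decay of the oscillation.
      # When gait is being initiated the irregularity persists to the end
      # of the transition (the first strides are unsteady); between two
      # postures the burst is symmetric.
      b <- bscale * if (cls_from == "static") {
        if (cls_to == "dynamic")
          burst_amplitude * sin(pmin(alpha / 0.5, 1) * pi / 2)
        else
          burst_amplitude * sin(pi * alpha)
      } else rep(0, dur)
      if (cls_to == "static") {
        # terminal weight settling: the body keeps swaying above the
        # static floor until the labelled end of the transition
        b <- pmax(b, 0.3 * bscale * sin(pi * pmax((alpha - 0.7) / 0.3, 0)))
      }
    } else {
      block <- matrix(regime_row(schedule$activity[k]), dur,
                      length(par_cols), byrow = TRUE,
                      dimnames = list(NULL, par_cols))
      b <- rep(0, dur)
      w <- rep(0, dur)
      if (activity_class(schedule$activity[k]) == "static") {
        # postures are not perfectly still: sparse fidgets (weight shifts,
        # small leg adjustments), mostly a smooth tilt excursion with a
        # slight acceleration ripple; the windowed acc_all STD stays well
        # below the 0.1 m/s^2 static threshold
        n_f <- stats::rpois(1, dur / (4 * fs))
        for (f in seq_len(n_f)) {
          flen <- min(dur, 25L + stats::rpois(1, 10))
          fat <- sample.int(max(1L, dur - flen), 1)
          idx <- fat + seq_len(flen) - 1L
          hump <- sin(pi * seq_len(flen) / (flen + 1))
          b[idx] <- pmax(b[idx], stats::runif(1, 0.03, 0.10) * hump)
        }
      }
    }
    par <- rbind(par, block)
    label <- c(label, rep(schedule$activity[k], dur))
    segment <- c(segment, rep(k, dur))
    burst <- c(burst, b)
    wobble <- c(wobble, w)
  }
  n <- nrow(par)
  # unsteady first strides: the initiation burst decays through the first
  # second of gait following a static-to-dynamic transition
  seg_end0 <- cumsum(schedule$duration)
  for (k in seq_len(nrow(schedule))) {
    if (schedule$activity[k] != "Transition" || is.na(schedule$from[k])) next
    if (activity_class(schedule$from[k]) == "static" &&
        activity_class(schedule$to[k]) == "dynamic" && k < nrow(schedule)) {
      m <- min(as.integer(fs), schedule$duration[k + 1L])
      idx <- seg_end0[k] + seq_len(m)
      burst[idx] <- pmax(burst[idx],
                         burst_amplitude * (1 - seq_len(m) / (m + 1)))
    }
  }
  # anticipatory gait modulation around postural boundaries: locomotion
  # adjacent to a static-involving transition starts slightly weak
  # (warm-up) or tapers off before stopping, ramping 0.4 <-> 1.0 of the
  # nominal amplitude over ~1.5 s; this extends the monotone STD ramp of the
  # transition into the flanking gait
  relamp <- rep(1, n)
  seg_end <- cumsum(schedule$duration)
  seg_start <- seg_end - schedule$duration + 1L
  ramp_len <- as.integer(1.5 * fs)
  for (k in seq_len(nrow(schedule))) {
    act <- schedule$activity[k]
    if (act == "Transition" || activity_class(act) != "dynamic") next
    dur <- schedule$duration[k]
    m <- min(ramp_len, dur)
    ramp <- 0.4 + 0.6 * (seq_len(m) - 1L) / max(1L, m - 1L)
    if (k > 1L && schedule$activity[k - 1L] == "Transition" &&
        activity_class(schedule$from[k - 1L]) == "static") {
      idx <- seg_start[k] + seq_len(m) - 1L
      relamp[idx] <- ramp
    }
    if (k < nrow(schedule) && schedule$activity[k + 1L] == "Transition" &&
        activity_class(schedule$to[k + 1L]) == "static") {
      idx <- seg_end[k] - m + seq_len(m)
      relamp[idx] <- rev(ramp)
    }
  }
  # postural-adjustment tilt for mixed static/dynamic transitions: when
  # initiating movement the weight shift starts ~0.5 s before the labelled
  # onset and spans the first 70% of the transition; when coming to rest
  # the settling sway spans the last 70% and dies out ~0.5 s after the
  # labelled end. The tilt rotates gravity only, so it perturbs the
  # per-axis features without adding acc_all variance.
  lead <- as.integer(0.5 * fs)
  seg_end1 <- cumsum(schedule$duration)
  seg_start1 <- seg_end1 - schedule$duration + 1L
  for (k in seq_len(nrow(schedule))) {
    if (schedule$activity[k] != "Transition" || is.na(schedule$from[k])) next
    cf <- activity_class(schedule$from[k]); ct <- activity_class(schedule$to[k])
    dur <- schedule$duration[k]
    if (cf == "static" && ct == "dynamic") {
      span <- max(1L, seg_start1[k] - lead):
        min(n, seg_start1[k] + as.integer(0.7 * dur) - 1L)
    } else if (cf == "dynamic" && ct == "static") {
      span <- max(1L, seg_start1[k] + as.integer(0.3 * dur)):
        min(n, seg_end1[k] + lead)
    } else next
    hump <- sin(pi * seq_along(span) / (length(span) + 1L))
    wobble[span] <- pmax(wobble[span], wsc[k] * hump)
  }
  # apply the postural-adjustment tilt (up to ~15 degrees) to the gravity
  # orientation in the sagittal plane
  ang <- 15 * pi / 180 * wobble
  ox <- par[, "orient_x"]; oz <- par[, "orient_z"]
  par[, "orient_x"] <- ox * cos(ang) + oz * sin(ang)
  par[, "orient_z"] <- -ox * sin(ang) + oz * cos(ang)
  # stride-to-stride gait variability: slow multiplicative modulation of
  # amplitude (and mildly of cadence) with ~1 s correlation length
  amp <- par[, "acc_amplitude"] * relamp *
    (1 + gait_variability * smooth_noise(n, span = as.integer(fs)))
  freq <- par[, "acc_frequency"] *
    (1 + 0.05 * smooth_noise(n, span = as.integer(fs)))
  phase <- cumsum(2 * pi * freq / fs)
  osc <- function(off) amp * sin(phase + off)
  bst <- function() burst * smooth_noise(n, span = 5L)
  acc_x <- par[, "orient_x"] * gravity + osc(0) + bst() +
    stats::rnorm(n, 0, par[, "acc_noise_sd"])
  acc_y <- par[, "orient_y"] * gravity + osc(2 * pi / 3) + bst() +
    stats::rnorm(n, 0, par[, "acc_noise_sd"])
  acc_z <- par[, "orient_z"] * gravity + osc(4 * pi / 3) + bst() +
    stats::rnorm(n, 0, par[, "acc_noise_sd"])
  pressure <- baro_base + cumsum(par[, "baro_drift"]) / fs
  bi <- seq(1L, n, by = baro_factor)
  braw <- pressure[bi] + stats::rnorm(length(bi), 0, par[bi, "baro_noise_sd"])
  baro <- upsample_barometer(braw, baro_factor)[seq_len(n)]
  sensor_stream(t = (seq_len(n) - 1) / fs, acc_x, acc_y, acc_z, baro,
                label = label, segment = segment)
}

# The seven diagram-allowed pairs in a fixed order.
allowed_pairs <- function() {
  rbind(c("Standing", "Walking"),
        c("Standing", "Upstairs"),
        c("Standing", "Downstairs"),
        c("Sitting",  "Standing"),
        c("Lying",    "Standing"),
        c("Walking",  "Running"),
        c("Walking",  "QuickWalk"))
}

#' Generate the synthetic transition benchmark
#'
#' Produces `n_sequences` labelled streams, each alternating two basic
#' activities with transitions in between (`B1, T, B2, T, B1, T, B2`), the
#' pattern of a transition-collection session. Pairs cycle through the seven
#' diagram-allowed transitions, so every transition embedded in the benchmark
#' is plausible. Each sequence is about `total_points` frames (3 min at 50 Hz
#' by default); basic segments share the residual length after the pair's
#' transition durations are set.
#'
#' @param n_sequences number of sequences (>= 1).
#' @param seed integer master seed; sequence `s` uses `seed * 1000 + s`.
#' @param total_points approximate frames per sequence.
#' @param regimes a [default_regimes()] table.
#' @param durations transition durations, frames.
#' @return List of class `"har_benchmark"`: `streams` (list of labelled
#'   [sensor_stream()]s) and `manifest`, a data.frame with one row per
#'   segment (`sequence`, `segment`, `activity`, `from`, `to`, `start`,
#'   `end` 0-based frame bounds, `pair_type` for transitions:
#'   `"static_dynamic"`, `"static_static"` or `"dynamic_dynamic"`).
#' @export
generate_benchmark <- function(n_sequences = 10L, seed = 1L,
                               total_points = 9000L,
                               regimes = default_regimes(),
                               durations = default_transition_durations()) {
  n_sequences <- as.integer(n_sequences)
  if (is.na(n_sequences) || n_sequences < 1L) stop("n_sequences must be >= 1")
  pairs <- allowed_pairs()
  streams <- vector("list", n_sequences)
  manifest <- list()
  for (s in seq_len(n_sequences)) {
    pr <- pairs[(s - 1L) %% nrow(pairs) + 1L, ]
    acts <- c(pr[1], pr[2], pr[1], pr[2])
    td <- durations[[pair_key(pr[1], pr[2])]]
    basic_dur <- max(200L, (total_points - 3L * td) %/% 4L)
    sched <- schedule_pattern(acts, basic_dur, durations)
    set.seed(seed * 1000L + 500L + s)
    subj <- sample_subject()
    st <- generate_stream(sched, regimes, seed = seed * 1000L + s,
                          subject = subj)
    streams[[s]] <- st
    ends <- cumsum(sched$duration)
    manifest[[s]] <- data.frame(
      sequence = s, segment = seq_len(nrow(sched)),
      activity = sched$activity, from = sched$from, to = sched$to,
      start = ends - sched$duration, end = ends - 1L,
      pair_type = ifelse(sched$activity == "Transition", {
        cls <- activity_class(c(pr[1], pr[2]))
        if (all(cls == "static")) "static_static"
        else if (all(cls == "dynamic")) "dynamic_dynamic"
        else "static_dynamic"
      }, NA_character_))
  }
  structure(list(streams = streams, manifest = do.call(rbind, manifest)),
            class = "har_benchmark")
}

#' Generate synthetic training collections
#'
#' Emulates a data-collection session: one pure stream per basic activity
#' (3 min at 50 Hz; 80 s for the stair activities) plus one
#' transition-collection sequence per allowed pair, in which the subject
#' alternates the two activities for about 3 min, yielding roughly ten
#' transitions per pair sequence.
#'
#' @param seed integer master seed.
#' @param n_subjects number of simulated subjects contributing to the
#'   collection; per-activity frames are split evenly across them.
#' @param basic_points total frames per basic activity.
#' @param stairs_points total frames for the Upstairs/Downstairs activities.
#' @param pair_points approximate frames per transition pair sequence.
#' @param regimes,durations as in [generate_benchmark()].
#' @return Named list: `pure` (streams named `activity.subject`) and `pairs`
#'   (streams named by pair key).
#' @export
generate_training_streams <- function(seed = 1L, n_subjects = 5L,
                                      basic_points = 9000L,
                                      stairs_points = 4000L,
                                      pair_points = 9000L,
                                      regimes = default_regimes(),
                                      durations = default_transition_durations()) {
  set.seed(seed * 1000L + 99L)
  subjects <- replicate(n_subjects, sample_subject(), simplify = FALSE)
  pure <- list()
  for (i in seq_along(activity_levels())) {
    act <- activity_levels()[i]
    npts <- if (act %in% c("Upstairs", "Downstairs")) stairs_points else basic_points
    per <- as.integer(npts) %/% n_subjects
    for (s in seq_len(n_subjects)) {
      sched <- data.frame(activity = act, duration = per,
                          from = NA_character_, to = NA_character_)
      pure[[paste(act, s, sep = ".")]] <-
        generate_stream(sched, regimes, seed = seed * 1000L + 100L + 10L * i + s,
                        subject = subjects[[s]])
    }
  }
  pairs <- list()
  ap <- allowed_pairs()
  for (j in seq_len(nrow(ap))) {
    a <- ap[j, 1]; b <- ap[j, 2]
    td <- durations[[pair_key(a, b)]]
    n_trans <- 9L
    acts <- rep(c(a, b), length.out = n_trans + 1L)
    basic_dur <- max(150L, (pair_points - n_trans * td) %/% (n_trans + 1L))
    sched <- schedule_pattern(acts, basic_dur, durations)
    pairs[[pair_key(a, b)]] <-
      generate_stream(sched, regimes, seed = seed * 1000L + 200L + j,
                      subject = subjects[[(j - 1L) %% n_subjects + 1L]])
  }
  list(pure = pure, pairs = pairs)
}

#' Write a benchmark to disk
#'
#' Writes each stream as a full-precision CSV (see [write_stream()]) plus a
#' JSON manifest of segment boundaries, the on-disk layout consumed by the
#' command-line interface.
#'
#' @param bench a [generate_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "har_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(bench$streams)) {
    write_stream(bench$streams[[s]],
                 file.path(dir, sprintf("sequence_%03d.csv", s)))
  }
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}

# Unit-variance band-limited noise: moving average of white noise over
# `span` frames, rescaled; circular filter keeps the edges defined.
smooth_noise <- function(n, span) {
  span <- max(2L, as.integer(span))
  x <- stats::filter(stats::rnorm(n + span), rep(1 / span, span),
                     circular = TRUE)
  x <- as.numeric(x)[seq_len(n)]
  x / sqrt(1 / span)
}

# Apply subject-level scales and mounting tilt to a regime table.
apply_subject <- function(regimes, subject) {
  r <- regimes
  r$acc_amplitude <- r$acc_amplitude * subject$gait_scale
  r$acc_frequency <- r$acc_frequency * subject$cadence_scale
  r$acc_noise_sd <- r$acc_noise_sd * subject$noise_scale
  a <- subject$tilt_deg * pi / 180
  ox <- r$orient_x; oz <- r$orient_z
  r$orient_x <- ox * cos(a) + oz * sin(a)
  r$orient_z <- -ox * sin(a) + oz * cos(a)
  r
}

#' Jitter activity-label boundaries
#'
#' Shifts every internal label boundary of a labelled stream by a uniform
#' random offset of up to `max_shift` frames, emulating the imprecision of
#' manual annotation of continuous recordings (the signal itself is
#' untouched). Typically applied to training collections so that classifier
#' confidence near activity boundaries reflects realistic labelling noise.
#'
#' @param stream a labelled [sensor_stream()].
#' @param max_shift maximum boundary shift in frames (default 15, i.e.
#'   0.3 s at 50 Hz).
#' @return The stream with jittered `label` (and `segment`) columns.
#' @export
jitter_labels <- function(stream, max_shift = 15L) {
  if (!"label" %in% names(stream)) stop("stream carries no labels")
  lab <- stream$label
  seg <- if ("segment" %in% names(stream)) stream$segment else
    cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
  r <- rle(seg)
  bounds <- cumsum(r$lengths)
  n_b <- length(bounds) - 1L
  if (n_b < 1L) return(stream)
  shift <- sample(seq(-max_shift, max_shift), n_b, replace = TRUE)
  new_bounds <- pmin(nrow(stream) - 1L, pmax(1L, bounds[seq_len(n_b)] + shift))
  new_bounds <- cummax(new_bounds)  # keep segment order
  lens <- diff(c(0L, new_bounds, nrow(stream)))
  stream$label <- rep(lab[bounds], lens)
  if ("segment" %in% names(stream)) stream$segment <- rep(r$values, lens)
  stream
}
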