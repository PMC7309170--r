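test_that("the difference series is the lagged first difference", {
  expect_equal(diff_series(c(0.1, 0.3, 0.2)), c(0.2, -0.1))
  expect_equal(diff_series(rep(0.5, 6)), rep(0, 5))
  for (n in 2:10) expect_length(diff_series(rnorm(n)), n - 1)
  expect_error(diff_series(0.1), "at least 2")
})

test_that("the four gate factors follow the printed rules", {
  expect_equal(unname(compute_theta(0.2, 0.15, 0.12, 0.95)), c(1, 1, 1, 0.95))
  # zero product is not > 0; low confidence clamps to 0.6
  expect_equal(unname(compute_theta(0.0, 0.15, 0.12, 0.5)), c(0, 1, 1, 0.6))
  # a shared negative trend counts the same as a positive one
  expect_equal(unname(compute_theta(-0.2, -0.15, -0.12, 1.0)), c(1, 1, 1, 1.0))
  # the change-magnitude indicator is strict
  expect_equal(compute_theta(0.2, 0.1, 0.2, 1)[["theta3"]], 0)
})

test_that("gate score matches direct evaluation over the whole factor lattice", {
  w <- gate_weights()
  direct <- function(t1, t2, t3, t4) 0.5 * t1 + 0.4 * t2 + 0.35 * t3 - (1 - t4) * 0.625
  for (t1 in 0:1) for (t2 in 0:1) for (t3 in 0:1)
    for (t4 in c(0.6, 0.7, 0.8, 0.9, 0.952, 1.0)) {
      th <- c(theta1 = t1, theta2 = t2, theta3 = t3, theta4 = t4)
      r <- gate_score(th, w)
      expect_identical(r, direct(t1, t2, t3, t4))
      fires <- r >= w$r_threshold
      expect_identical(fires, t1 == 1 && t2 == 1 && t3 == 1 && t4 >= 0.952)
    }
  expect_equal(gate_score(c(theta1 = 1, theta2 = 1, theta3 = 1, theta4 = 1)), 1.25)
  expect_equal(gate_score(c(theta1 = 0, theta2 = 0, theta3 = 0, theta4 = 0.6)), -0.25)
  expect_equal(gate_score(c(theta1 = 1, theta2 = 1, theta3 = 1, theta4 = 0.6)), 1.00)
})

test_that("single steps of the state machine follow the entry/exit rules", {
  w <- gate_weights()
  pr <- function(best, p) {
    probs <- rep((1 - p) / 7, 8)
    names(probs) <- activity_levels()
    probs[best] <- p
    probs
  }
  # static entry: high STD and scattered probabilities
  s <- transition_state("Standing")
  r <- stdta_step(s, std_i = 0.5, 0, 0, 0, pr("Walking", 0.7), w)
  expect_equal(r$label, "Transition")
  expect_true(r$state$intrans)
  expect_equal(r$state$count, 1L)

  # quiet static window: nothing happens
  r <- stdta_step(transition_state("Standing"), 0.05, 0, 0, 0, pr("Standing", 0.99), w)
  expect_equal(r$label, "Standing")
  expect_false(r$state$intrans)
  expect_equal(r$state$count, 0L)

  # dynamic branch: consistent trend with confident classifier fires the gate
  r <- stdta_step(transition_state("Walking"), 0.6, 0.2, 0.15, 0.12, pr("Walking", 1.0), w)
  expect_equal(r$label, "Transition")
  expect_equal(r$r, 1.25)

  # ongoing transition ends when the classifier becomes confident
  s <- transition_state("Transition")
  s$intrans <- TRUE; s$count <- 1L
  r <- stdta_step(s, 0.5, 0.01, -0.01, 0.01, pr("Walking", 0.95), w)
  expect_equal(r$label, "Walking")
  expect_false(r$state$intrans)
  expect_equal(r$state$count, 0L)
})

test_that("a transition cannot outlast the duration cutoff", {
  w <- gate_weights()
  probs <- rep(1 / 8, 8); names(probs) <- activity_levels()
  s <- transition_state("Standing")
  labels <- character(12)
  for (i in 1:12) {
    r <- stdta_step(s, std_i = 0.5, 0, 0, 0, probs, w)
    labels[i] <- r$label
    s <- r$state
    expect_lte(s$count, w$count_max)
    if (!s$intrans) expect_equal(s$count, 0L)
  }
  # the cutoff forces at least one exit inside 12 windows
  expect_true(any(labels != "Transition"))
})

test_that("run_stdta is deterministic, total and respects boundaries", {
  set.seed(8)
  n <- 40
  probs <- matrix(runif(n * 8), n, 8)
  probs <- probs / rowSums(probs)
  colnames(probs) <- activity_levels()
  stds <- abs(rnorm(n, 0.3, 0.2))
  t1 <- run_stdta(probs, stds)
  t2 <- run_stdta(probs, stds)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), n)
  expect_true(all(t1$count <= gate_weights()$count_max))
  expect_true(all(t1$count[!t1$intrans] == 0))

  # a single window has no trend: the classifier argmax is emitted
  one <- run_stdta(probs[1, , drop = FALSE], 0.05)
  expect_equal(one$label, colnames(probs)[which.max(probs[1, ])])

  expect_error(run_stdta(probs, stds[-1]), "lengths differ")
})

test_that("an all-static stream yields no transition labels", {
  n <- 30
  probs <- matrix(0.01, n, 8); colnames(probs) <- activity_levels()
  probs[, "Standing"] <- 1 - 0.07
  stds <- rep(0.015, n)
  tl <- run_stdta(probs, stds)
  expect_true(all(tl$label == "Standing"))
})

test_that("transition spans carry their flanking basic activities", {
  labels <- c("Standing", "Transition", "Transition", "Walking", "Walking")
  sp <- stdta:::transition_spans(labels)
  expect_equal(sp$before, "Standing")
  expect_equal(sp$after, "Walking")
  expect_equal(sp$from, 2L)
  expect_equal(sp$to, 3L)
})

test_that("least squares recovers planted gate weights exactly", {
  set.seed(123)
  w_star <- c(0.5, 0.4, 0.35, -0.625)
  th <- cbind(sample(0:1, 200, TRUE), sample(0:1, 200, TRUE),
              sample(0:1, 200, TRUE), runif(200, 0.6, 1))
  y <- as.numeric(th %*% w_star)
  w_hat <- fit_gate_weights(th, y)
  expect_equal(unname(w_hat), w_star, tolerance = 1e-6)

  expect_equal(unname(fit_gate_weights(th, rep(0, 200))), rep(0, 4),
               tolerance = 1e-12)
  expect_error(fit_gate_weights(th[, c(1, 1, 2, 3)], y), "rank")
  expect_error(fit_gate_weights(th[, 1:3], y[1:200]), "4 columns")
})

test_that("the transition diagram has 7 edges and excludes implausible pairs", {
  d <- transition_diagram()
  expect_equal(sum(d), 14)  # directed transitions
  expect_true(transition_allowed("Lying", "Standing", d))
  expect_false(transition_allowed("Lying", "Running", d))
  expect_true(transition_allowed("Standing", "Walking", d))
  expect_error(transition_allowed("Lying", "Lying", d), "distinct")
  expect_true(isSymmetric(unclass(d)))
})

test_that("diagram enforcement restricts labels to reachable activities", {
  n <- 6
  probs <- matrix(0.001, n, 8); colnames(probs) <- activity_levels()
  probs[, "Running"] <- 0.95   # implausible directly after Lying
  probs[1, ] <- 0.001; probs[1, "Lying"] <- 0.95
  probs <- probs / rowSums(probs)
  stds <- rep(0.01, n)
  free <- run_stdta(probs, stds, prev_label = "Lying")
  expect_equal(free$label[2], "Running")
  gated <- run_stdta(probs, stds, prev_label = "Lying", enforce_diagram = TRUE)
  expect_false("Running" %in% gated$label[2])
  expect_true(gated$label[2] %in% c("Lying", "Standing"))
})
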