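test_that("generation is deterministic given the seed", {
  sched <- schedule_pattern(c("Standing", "Walking"), 400)
  s1 <- generate_stream(sched, seed = 5)
  s2 <- generate_stream(sched, seed = 5)
  expect_identical(s1, s2)
  s3 <- generate_stream(sched, seed = 6)
  expect_false(identical(s1$acc_x, s3$acc_x))
})

test_that("static regimes stay under the 0.1 STD threshold with gravity-level mean", {
  sched <- data.frame(activity = "Standing", duration = 500L,
                      from = NA_character_, to = NA_character_)
  st <- generate_stream(sched, seed = 1)
  fm <- feature_matrix(st)
  expect_true(all(std_series(fm) < 0.1))
  expect_true(all(fm[, "mean_acc_all"] > 9 & fm[, "mean_acc_all"] < 13))
})

test_that("dynamic regimes produce window STDs in the documented range", {
  for (act in c("Walking", "QuickWalk", "Running")) {
    sched <- data.frame(activity = act, duration = 500L,
                        from = NA_character_, to = NA_character_)
    st <- generate_stream(sched, seed = 2)
    stds <- std_series(feature_matrix(st))
    expect_true(all(stds > 0.1 & stds <= 2.2), label = act)
  }
})

test_that("stair regimes drift the barometer monotonically in expectation", {
  for (cfg in list(c("Upstairs", -1), c("Downstairs", 1))) {
    sched <- data.frame(activity = cfg[1], duration = 2000L,
                        from = NA_character_, to = NA_character_)
    st <- generate_stream(sched, seed = 3)
    slope <- coef(lm(st$baro ~ st$t))[2]
    expect_equal(sign(unname(slope)), as.numeric(cfg[2]), label = cfg[1])
  }
})

test_that("transition segments show a same-sign run in the STD differences", {
  sched <- schedule_pattern(c("Standing", "Walking"), 600)
  st <- generate_stream(sched, seed = 4)
  fm <- feature_matrix(st)
  d <- diff_series(std_series(fm))
  tw <- which(attr(fm, "truth") == "Transition")
  # around the ramp the differences keep one sign over >= 3 consecutive steps
  around <- d[max(1, min(tw) - 3):min(length(d), max(tw) + 1)]
  runs <- rle(sign(around[abs(around) > 0.02]))
  expect_gte(max(runs$lengths), 3)
})

test_that("schedules validate their activities and durations", {
  expect_error(schedule_pattern(c("Standing", "Standing"), 100), "differ")
  expect_error(schedule_pattern(c("Lying", "Running"), 100), "no duration")
  sched <- schedule_pattern(c("Standing", "Walking", "Standing"), 300)
  expect_equal(sched$activity,
               c("Standing", "Transition", "Walking", "Transition", "Standing"))
  expect_equal(sched$duration[c(2, 4)], rep(45L, 2))
  bad <- data.frame(activity = "Flying", duration = 100L,
                    from = NA_character_, to = NA_character_)
  expect_error(generate_stream(bad), "not in regime table")
})

test_that("the benchmark embeds only diagram-allowed transitions", {
  bench <- generate_benchmark(8, seed = 3, total_points = 2200)
  expect_length(bench$streams, 8)
  d <- transition_diagram()
  trans <- bench$manifest[bench$manifest$activity == "Transition", ]
  for (k in seq_len(nrow(trans))) {
    expect_true(transition_allowed(trans$from[k], trans$to[k], d))
  }
  expect_error(generate_benchmark(0), "n_sequences")
})

test_that("benchmark sequences alternate basic and transition segments", {
  bench <- generate_benchmark(2, seed = 4, total_points = 2200)
  m <- bench$manifest[bench$manifest$sequence == 1, ]
  expect_equal(m$activity[c(1, 3, 5, 7)] == "Transition", rep(FALSE, 4))
  expect_equal(m$activity[c(2, 4, 6)], rep("Transition", 3))
  # the two basic activities alternate, as in a paired collection session
  basics <- m$activity[m$activity != "Transition"]
  expect_length(unique(basics), 2)
  expect_true(all(basics[1:3] != basics[2:4]))
})

test_that("manifest segment bounds agree with the per-frame labels", {
  bench <- generate_benchmark(2, seed = 5, total_points = 2200)
  for (s in 1:2) {
    st <- bench$streams[[s]]
    m <- bench$manifest[bench$manifest$sequence == s, ]
    expect_equal(nrow(st), m$end[nrow(m)] + 1L)
    for (k in seq_len(nrow(m))) {
      expect_true(all(st$label[(m$start[k] + 1):(m$end[k] + 1)] == m$activity[k]))
    }
    ws <- sliding_windows(st)
    expect_equal(nrow(ws), (nrow(st) - 50) %/% 25 + 1)
  }
})

test_that("label jitter moves boundaries without touching the signal", {
  sched <- schedule_pattern(c("Standing", "Walking"), 400)
  st <- generate_stream(sched, seed = 6)
  set.seed(1)
  jt <- jitter_labels(st, max_shift = 15)
  expect_identical(jt$acc_x, st$acc_x)
  expect_setequal(unique(jt$label), unique(st$label))
  moved <- which(jt$label != st$label)
  b1 <- which(diff(as.integer(factor(st$label, levels = unique(st$label)))) != 0)
  expect_true(all(vapply(moved, function(i) min(abs(i - b1)) <= 16, TRUE)))
})

test_that("benchmark files round-trip through the on-disk layout", {
  bench <- generate_benchmark(1, seed = 7, total_points = 1200)
  dir <- withr::local_tempdir()
  write_benchmark(bench, dir)
  expect_true(file.exists(file.path(dir, "sequence_001.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_stream(file.path(dir, "sequence_001.csv"))
  expect_identical(back$acc_z, bench$streams[[1]]$acc_z)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(nrow(man), nrow(bench$manifest))
})
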