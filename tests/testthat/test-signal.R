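test_that("write/read round trip reproduces channels bit-identically", {
  st <- toy_stream(60, seed = 3, label = rep(c("Standing", "Walking"), each = 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(st, path)
  back <- read_stream(path)
  for (ch in c("t", "acc_x", "acc_y", "acc_z", "baro")) {
    expect_identical(back[[ch]], st[[ch]])
  }
  expect_identical(back$label, st$label)
})

test_that("reader reports missing columns and bad cells with positions", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,acc_x,acc_y,acc_z", "0,1,2,3"), path)
  expect_error(read_stream(path), "baro")

  writeLines(c("t,acc_x,acc_y,acc_z,baro",
               "0,1,2,3,1013", "0.02,oops,2,3,1013"), path)
  expect_error(read_stream(path), "line 2")
})

test_that("separate 5 Hz barometer file is upsampled and aligned on load", {
  acc <- withr::local_tempfile(fileext = ".csv")
  bar <- withr::local_tempfile(fileext = ".csv")
  n <- 40
  utils::write.csv(data.frame(t = (0:(n - 1)) / 50, acc_x = 0, acc_y = 0,
                              acc_z = 9.81), acc, row.names = FALSE)
  utils::write.csv(data.frame(t = c(0, 0.2, 0.4, 0.6),
                              baro = c(1013.1, 1013.2, 1013.3, 1013.4)),
                   bar, row.names = FALSE)
  st <- read_stream(acc, baro_path = bar)
  expect_equal(nrow(st), 40)
  expect_equal(st$baro, rep(c(1013.1, 1013.2, 1013.3, 1013.4), each = 10))
})

test_that("barometer upsampling repeats each sample ten times in order", {
  expect_equal(upsample_barometer(1013.2), rep(1013.2, 10))
  expect_equal(upsample_barometer(c(1, 2)), rep(c(1, 2), each = 10))
  expect_equal(upsample_barometer(numeric(0)), numeric(0))
  for (n in 1:20) {
    x <- rnorm(n)
    up <- upsample_barometer(x)
    expect_length(up, 10L * n)
    expect_equal(unique(up), unique(x))
    r <- rle(up)
    expect_true(all(r$lengths %% 10 == 0 | duplicated(x)[1]))
  }
})

test_that("window starts, counts and boundaries follow the stride rule", {
  st <- toy_stream(125)
  expect_equal(sliding_windows(st)$start, c(0, 25, 50, 75))
  expect_equal(nrow(sliding_windows(toy_stream(50))), 1)
  expect_equal(nrow(sliding_windows(toy_stream(49))), 0)
  expect_error(sliding_windows(st, size = 0), "size")
  expect_error(sliding_windows(st, size = 50, step = 60), "step")

  # overlap and coverage invariants
  ws <- sliding_windows(st, size = 50, step = 25)
  d <- diff(ws$start)
  expect_true(all(d == 25))
  expect_equal(max(ws$start) + 50, 125)
})

test_that("window count matches brute-force enumeration over n", {
  brute <- function(n, size, step) {
    cnt <- 0; s <- 0
    while (s + size <= n) { cnt <- cnt + 1; s <- s + step }
    cnt
  }
  for (n in c(1, 25, 49, 50, 51, 74, 75, 76, 100, 123, 300)) {
    st <- toy_stream(n)
    expect_equal(nrow(sliding_windows(st)), brute(n, 50, 25), info = n)
    expect_equal(nrow(sliding_windows(st, size = 30, step = 10)),
                 brute(n, 30, 10), info = n)
  }
})

test_that("window truth is the majority frame label with ties to Transition", {
  lab <- c(rep("Standing", 60), rep("Transition", 25), rep("Walking", 40))
  st <- toy_stream(125, label = lab)
  ws <- sliding_windows(st)
  # window [50,100): 10 Standing + 25 Transition + 15 Walking -> Transition
  expect_equal(ws$truth[ws$start == 50], "Transition")
  expect_equal(ws$truth[ws$start == 0], "Standing")
  expect_equal(ws$truth[ws$start == 75], "Walking")

  # exact tie between two basic labels breaks toward the lower class index
  lab2 <- c(rep("Walking", 25), rep("Sitting", 100))
  st2 <- toy_stream(125, label = lab2)
  expect_equal(sliding_windows(st2)$truth[1], "Sitting")  # A01 before A04
})

test_that("generated fixture preserves frame count and labels through I/O", {
  sched <- data.frame(activity = "Standing", duration = 500L,
                      from = NA_character_, to = NA_character_)
  st <- generate_stream(sched, seed = 11)
  expect_equal(nrow(st), 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(st, path)
  back <- read_stream(path)
  expect_equal(nrow(back), 500)
  expect_identical(back$label, st$label)
})

test_that("stream validation rejects broken inputs", {
  expect_error(sensor_stream(t = c(0, 0), acc_x = 1:2, acc_y = 1:2,
                             acc_z = 1:2, baro = 1:2), "increasing")
  expect_error(sensor_stream(t = 0:1, acc_x = c(1, NA), acc_y = 1:2,
                             acc_z = 1:2, baro = 1:2), "finite")
  expect_error(sensor_stream(t = 0:1, acc_x = 1:2, acc_y = 1:2,
                             acc_z = 1:2, baro = 1:2, label = "x"),
               "one entry per frame")
})
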