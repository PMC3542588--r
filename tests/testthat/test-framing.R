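test_that("optimal window length is the temporal smoothing window size", {
  expect_equal(optimal_window_length(10000, 0.1), 1000L)
  expect_equal(optimal_window_length(44421, 0.03), 1333L)
  expect_equal(optimal_window_length(100, 1.0), 100L)
  expect_error(optimal_window_length(100, 1.2), "span")
})

test_that("the first window holds L records extended to whole days", {
  d <- uniform_dataset(days = 100, per_day = 10)
  w <- first_window(d, 1000L)          # L = n: whole dataset
  expect_equal(w$length, 1000L)
  w2 <- first_window(d, 95L)           # record 95 is mid-day 10
  expect_equal(w2$indices, 1:100)
  expect_equal(w2$first_day, 1L)
  expect_equal(w2$last_day, 10L)
  # hand case: records 4-7 share a day, L = 5 pulls in all of them
  ds <- ed_dataset(data.frame(x = runif(9), y = runif(9),
                              day = c(1, 2, 3, 4, 4, 4, 4, 8, 9),
                              outcome = rep(c(0, 1), length.out = 9),
                              age = runif(9)))
  w3 <- first_window(ds, 5L)
  expect_equal(w3$indices, 1:7)
  expect_error(first_window(ds, 10L), "exceeds")
})

test_that("median day is the day of the median record", {
  ds <- ed_dataset(data.frame(x = runif(7), y = runif(7),
                              day = c(1, 1, 2, 2, 3, 3, 3),
                              outcome = rep(c(0, 1), length.out = 7),
                              age = runif(7)))
  expect_equal(window_median_day(first_window(ds, 7L)), 2L)
  one <- ed_dataset(data.frame(x = 1, y = 1, day = 5, outcome = 1, age = 3))
  expect_equal(window_median_day(first_window(one, 1L)), 5L)
})

test_that("the worked example reproduces interval 25 and next median 60", {
  d <- worked_example_dataset()
  w1 <- first_window(d, 1000L)
  expect_equal(w1$length, 1000L)
  # span 0.3 of 1,000 records selects record 300, which falls on day 25
  expect_equal(inter_window_interval(d, w1, 0.3), 25L)
  # the median record (500) falls on day 35
  expect_equal(window_median_day(w1), 35L)
  # next median day = 35 + 25 = 60
  expect_equal(window_median_day(w1) + inter_window_interval(d, w1, 0.3), 60)
  # nth record on the first day floors the interval at 1
  expect_equal(inter_window_interval(d, w1, 0.001), 1L)
})

test_that("next_window grows whole days around the target median", {
  d <- uniform_dataset(days = 100, per_day = 10)
  # symmetric data: window of 50 records spans target day +/- 2
  w <- next_window(d, 50L, 50L)
  expect_equal(w$first_day, 48L)
  expect_equal(w$last_day, 52L)
  expect_equal(w$length, 50L)
  # L = 1: just the target day
  w1 <- next_window(d, 30L, 1L)
  expect_equal(c(w1$first_day, w1$last_day), c(30L, 30L))
  # equidistant tie annexes the earlier day first
  w2 <- next_window(d, 50L, 20L)
  expect_equal(c(w2$first_day, w2$last_day), c(49L, 50L))
  # a target day without records expands from the nearest populated day
  ds <- ed_dataset(data.frame(x = runif(6), y = runif(6),
                              day = c(1, 1, 2, 8, 9, 9),
                              outcome = rep(c(0, 1), 3), age = runif(6)))
  w3 <- next_window(ds, 5L, 2L)
  expect_equal(c(w3$first_day, w3$last_day), c(2L, 8L))
  expect_error(next_window(d, 2000L, 10L), "outside")
})

test_that("build_framing chains windows at a fixed interval to the last day", {
  d <- uniform_dataset(days = 100, per_day = 10)
  fr <- build_framing(d, temporal_span = 0.2, window_span = 0.5)
  expect_equal(fr$plan$L, 200L)
  # window 1 = days 1-20; record 100 of the window falls on relative day 10
  expect_equal(fr$plan$interval, 10L)
  expect_equal(window_median_day(fr$windows[[1]]), 10L)
  # planned medians advance by exactly the interval
  expect_true(all(diff(fr$plan$median_days) == 10L))
  # coverage: every record in at least one window, all windows >= L
  idx <- sort(unique(unlist(lapply(fr$windows, `[[`, "indices"))))
  expect_identical(idx, seq_len(nrow(d)))
  expect_true(all(vapply(fr$windows, `[[`, integer(1), "length") >= 200L))
  # contiguity: every record whose day is inside the window is a member
  for (w in fr$windows) {
    inside <- which(d$day >= w$first_day & d$day <= w$last_day)
    expect_identical(inside, w$indices)
  }
  # consecutive windows overlap in days
  for (i in seq_len(length(fr$windows) - 1))
    expect_lte(fr$windows[[i + 1]]$first_day, fr$windows[[i]]$last_day)
  # the series stops when a window reaches the final study day
  expect_equal(fr$windows[[length(fr$windows)]]$last_day, 100L)
  # determinism: no randomness in framing
  expect_identical(fr, build_framing(d, 0.2, 0.5))
})

test_that("a full-data temporal span gives a single window", {
  d <- uniform_dataset(days = 30, per_day = 5)
  fr <- build_framing(d, temporal_span = 1, window_span = 0.5)
  expect_length(fr$windows, 1)
  expect_equal(fr$windows[[1]]$length, nrow(d))
})

test_that("the five-year surveillance framing parameters give 127 planned windows", {
  s <- median_day_sequence(46, 14, 1810)
  expect_length(s, 127)
  expect_equal(s[1], 46L)
  expect_equal(s[127], 1810L)
  expect_true(all(diff(s) == 14L))
})
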