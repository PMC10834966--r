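test_that("gait events are found at threshold crossings", {
  f <- c(rep(0, 36), rep(100, 20), rep(0, 20), rep(100, 20), rep(0, 10))
  ev <- detect_gait_events(f)
  expect_s3_class(ev, "gait_events")
  expect_identical(ev$touchdown, c(37L, 77L))
  expect_identical(ev$toeoff, c(57L, 97L))
  expect_true(all(ev$toeoff > ev$touchdown))

  expect_error(detect_gait_events(rep(0, 100)), "never crosses")

  # scale invariance above threshold (step plateaus)
  ev2 <- detect_gait_events(3 * f)
  expect_identical(ev2$touchdown, ev$touchdown)
  expect_identical(ev2$toeoff, ev$toeoff)

  # incomplete leading stance (starts above threshold) is dropped
  ev3 <- detect_gait_events(c(rep(100, 10), rep(0, 10), rep(100, 10),
                              rep(0, 5)))
  expect_identical(ev3$touchdown, 21L)

  # synthetic 60-cycle force: brute-force crossing scan agrees
  rec <- generate_recording(default_truth(seed = 4))
  ev4 <- detect_gait_events(rec$force, rate = rec$force_rate)
  expect_length(ev4$touchdown, 60)
  expect_length(ev4$toeoff, 60)
  brute_td <- which(rec$force[-1] >= 50 & rec$force[-length(rec$force)] < 50) + 1
  expect_identical(ev4$touchdown, as.integer(brute_td))
})

test_that("debouncing merges threshold chatter", {
  # a 2-sample dip inside a stance plateau at 100 Hz
  f <- c(rep(0, 10), rep(100, 8), c(0, 0), rep(100, 8), rep(0, 10))
  raw <- detect_gait_events(f)
  expect_length(raw$touchdown, 2)
  deb <- detect_gait_events(f, rate = 100, debounce_s = 0.05)
  expect_length(deb$touchdown, 1)
  expect_identical(deb$toeoff, 29L)
})

test_that("spatiotemporal parameters follow from event arithmetic", {
  ev <- structure(list(touchdown = c(1L, 101L, 201L),
                       toeoff = c(26L, 126L, 226L)),
                  class = "gait_events")
  st <- spatiotemporal_params(ev, rate = 100)
  expect_equal(st$stance_time, c(0.25, 0.25))
  expect_equal(st$flight_time, c(0.75, 0.75))
  expect_equal(st$stride_frequency, c(1, 1))
  # stride period identity
  expect_equal(st$stance_time + st$flight_time, 1 / st$stride_frequency)

  # programmed 0.20 s / 0.15 s phases recovered within one force sample
  rec <- generate_recording(default_truth(n_cycles = 5, seed = 6))
  st2 <- spatiotemporal_params(detect_gait_events(rec$force), rate = 100)
  expect_true(all(abs(st2$stance_time - 0.20) <= 0.01))
  expect_true(all(abs(st2$flight_time - 0.15) <= 0.01))

  expect_error(spatiotemporal_params(
    structure(list(touchdown = 1L, toeoff = 10L), class = "gait_events"),
    rate = 100), "2 complete cycles")
})

test_that("the envelope cascade suppresses sub-50 Hz carriers and keeps
           rectified high-frequency power", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)

  expect_equal(filter_emg(matrix(0, 1, length(t)), rate),
               matrix(0, 1, length(t)))

  # 5 Hz sinusoid dies before rectification (50 Hz high-pass)
  x5 <- sin(2 * pi * 5 * t)
  y5 <- filter_emg(x5, rate)
  expect_lt(sqrt(mean(y5^2)) / sqrt(mean(x5^2)), 0.05)

  # 150 Hz sinusoid: rectification leaves a DC level ~ 2A/pi that the
  # 20 Hz low-pass preserves
  x150 <- sin(2 * pi * 150 * t)
  y150 <- filter_emg(x150, rate)
  mid <- seq(round(0.25 * length(t)), round(0.75 * length(t)))
  expect_gt(mean(y150[mid]), 0.5 * 2 / pi)
  expect_true(all(y150 >= 0))

  expect_error(filter_emg(x5, rate = 800), "exceed 1000")
})

test_that("amplitude normalization maps channels onto [0, 1]", {
  expect_equal(as.numeric(normalize_amplitude(matrix(c(2, 4, 6), 1))),
               c(0, 0.5, 1))
  m <- matrix(runif(20), 2)
  expect_equal(normalize_amplitude(normalize_amplitude(m)),
               normalize_amplitude(m))
  bad <- matrix(c(1, 1, 1, 2, 3, 4), 2, byrow = TRUE,
                dimnames = list(c("TA", "GM"), NULL))
  expect_error(normalize_amplitude(bad), "TA")
})

test_that("time normalization yields exactly 100 + 100 points per cycle", {
  rec <- generate_recording(default_truth(n_cycles = 60, seed = 8))
  ev <- detect_gait_events(rec$force)
  tensor <- time_normalize(rec$emg, ev, rec$emg_rate, rec$force_rate)
  expect_equal(dim(tensor$values), c(11, 200, 60))
  expect_equal(tensor$n_stance, 100)
  expect_equal(dim(as.matrix(tensor)), c(11, 12000))

  # constant envelope stays constant
  cst <- time_normalize(matrix(2, 1, ncol(rec$emg)), ev, rec$emg_rate,
                        rec$force_rate)
  expect_true(all(cst$values == 2))

  # closed-form check: a ramp over one stance resamples to a ramp
  f <- c(rep(0, 10), rep(100, 50), rep(0, 50), rep(100, 50), rep(0, 40))
  evr <- detect_gait_events(f)
  env <- numeric(length(f) * 20)  # 2000 Hz vs 100 Hz
  st_start <- (evr$touchdown[1] - 1) * 20 + 1
  st_end <- (evr$toeoff[1] - 1) * 20 + 1
  env[st_start:(st_end - 1)] <- seq(0, 1, length.out = st_end - st_start)
  tn <- time_normalize(matrix(env, 1), evr, 2000, 100)
  expected <- (seq_len(100) - 1) / 100 * (st_end - st_start) /
    (st_end - st_start - 1)
  expect_equal(as.numeric(tn$values[1, 1:100, 1]), expected,
               tolerance = 1e-6)
})

test_that("cycle selection keeps the trailing cycles in order", {
  rec <- generate_recording(default_truth(n_cycles = 20, seed = 9,
                                          noise_sigma = 0))
  ev <- detect_gait_events(rec$force)
  tensor <- time_normalize(rec$emg, ev, rec$emg_rate, rec$force_rate)
  expect_identical(select_last_cycles(tensor, 20)$values, tensor$values)
  last5 <- select_last_cycles(tensor, 5)
  expect_equal(last5$values, tensor$values[, , 16:20, drop = FALSE])
  expect_error(select_last_cycles(tensor, 60), "only 20 cycles")
})

test_that("full preprocessing yields values in [0, 1] with per-muscle max 1", {
  pp <- preprocess_recording(quick_recording(n_cycles = 25, seed = 10),
                             keep_cycles = 20)
  v <- pp$tensor$values
  expect_true(all(v >= 0 & v <= 1))
  for (i in seq_len(dim(v)[1])) {
    expect_equal(max(v[i, , ]), 1)
    expect_equal(min(v[i, , ]), 0)
  }
})
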