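jm <- default_joint_map()

test_that("co-contribution index hits its boundary cases exactly", {
  w <- c(TA = 0, GaM = 0, GaL = 0, SOL = 0, PL = 0, VM = 0, VL = 0,
         RF = 0.8, BF = 0, STSM = 0, GM = 0)
  expect_identical(co_contribution_index(w, jm, "hip"), 1)
  w2 <- w; w2["RF"] <- 0; w2["GM"] <- 0.5
  expect_identical(co_contribution_index(w2, jm, "hip"), 0)
  w3 <- c(RF = 0.4, VL = 0.8, VM = 0.6, STSM = 0.7, BF = 0.5)
  expect_identical(co_contribution_index(w3, jm, "knee"), 0.5)
  # scale invariance
  set.seed(31)
  w4 <- setNames(runif(11, 0.1, 1), names(w))
  expect_equal(co_contribution_index(3.7 * w4, jm, "ankle"),
               co_contribution_index(w4, jm, "ankle"))
  expect_error(co_contribution_index(w * 0, jm, "hip"), "zero")
})

test_that("center of activity respects the touchdown convention and
           circular shifts", {
  h <- numeric(200)
  h[1] <- 1
  expect_equal(center_of_activity(h), 0)
  h2 <- numeric(200); h2[101] <- 1
  expect_equal(center_of_activity(h2), 180)

  # symmetric bump at point 51: brute-force circular mean
  bump <- make_primitive(list(list(center = 51, width = 30, amplitude = 1)))
  expect_equal(center_of_activity(bump), 90, tolerance = 1 / 90)

  # equivariance: shifting by d points rotates the CoA by 1.8 * d degrees
  set.seed(32)
  h3 <- make_primitive(list(list(center = 40, width = 25, amplitude = 1)))
  for (d in c(10, 57, 133)) {
    shifted <- c(tail(h3, -d), head(h3, d))  # shift left by d
    delta <- (center_of_activity(h3) - center_of_activity(shifted)) %% 360
    expect_equal(delta, (360 * d / 200) %% 360, tolerance = 1e-6)
  }
  expect_error(center_of_activity(numeric(200)), "all-zero")
})

test_that("FWHM counts points above half of the min-subtracted maximum", {
  rect <- c(rep(0, 100), rep(1, 40), rep(0, 60))
  expect_identical(full_width_half_max(rect), 40L)

  # triangle on a 0.02 grid: exactly 49 points lie strictly above the
  # half maximum 0.5 (25 ascending incl. the peak + 24 descending; the
  # two grid points equal to 0.52 enter, the two at 0.50 do not)
  tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1],
           numeric(99))
  expect_identical(full_width_half_max(tri), 49L)
  expect_lte(abs(full_width_half_max(tri) - 50), 1)

  s <- sin(2 * pi * (0:199) / 200)
  expect_equal(full_width_half_max(s - min(s)), 100, tolerance = 1 / 100)

  # affine invariance
  bump <- make_primitive(list(list(center = 80, width = 35, amplitude = 1)))
  expect_identical(full_width_half_max(2.5 * bump + 3),
                   full_width_half_max(bump))
  expect_error(full_width_half_max(rep(1, 200)), "constant")
})

test_that("exceedance frequency counts per-cycle half-max crossings", {
  bump <- make_primitive(list(list(center = 50, width = 40, amplitude = 1)))
  identical_cycles <- matrix(bump, 200, 60)
  f <- exceedance_frequency(identical_cycles)
  expect_true(all(f %in% c(0, 1)))
  expect_equal(sum(f), full_width_half_max(bump))

  # a point exceeded in 30 of 60 cycles has frequency 0.5
  half <- cbind(matrix(bump, 200, 30),
                matrix(c(tail(bump, -100), head(bump, 100)), 200, 30))
  expect_equal(exceedance_frequency(half)[50], 0.5)

  # jittered bump centers: plateau of 1 with decreasing shoulders
  set.seed(33)
  jit <- vapply(1:60, function(i) {
    make_primitive(list(list(center = 50 + sample(-5:5, 1), width = 40,
                             amplitude = 1)))
  }, numeric(200))
  fj <- exceedance_frequency(jit)
  expect_equal(max(fj), 1)
  expect_true(any(fj > 0 & fj < 1))
  # brute-force per-cycle thresholding oracle
  brute <- rowMeans(apply(jit, 2, function(h) {
    x <- h - min(h); x > max(x) / 2
  }))
  expect_equal(fj, brute)
})

test_that("overlap frequency equals the brute-force indicator count", {
  b1 <- make_primitive(list(list(center = 60, width = 30, amplitude = 1)))
  b2 <- make_primitive(list(list(center = 75, width = 30, amplitude = 1)))
  b3 <- make_primitive(list(list(center = 160, width = 30, amplitude = 1)))
  m1 <- matrix(b1, 200, 10); m2 <- matrix(b2, 200, 10)
  m3 <- matrix(b3, 200, 10)

  # identical support: frequency 1 inside, 0 outside
  ov_same <- overlap_frequency(list(m1, m1))
  expect_true(all(ov_same %in% c(0, 1)))
  expect_equal(sum(ov_same), full_width_half_max(b1))

  # disjoint supports never overlap
  expect_true(all(overlap_frequency(list(m1, m3)) == 0))

  # three synergies with partial overlaps: exhaustive AND/count oracle
  ov <- overlap_frequency(list(m1, m2, m3))
  ind <- lapply(list(m1, m2, m3), function(m) {
    apply(m, 2, function(h) { x <- h - min(h); x > max(x) / 2 })
  })
  brute <- sapply(1:200, function(p) {
    mean(sapply(1:10, function(cc) {
      sum(ind[[1]][p, cc], ind[[2]][p, cc], ind[[3]][p, cc]) >= 2
    }))
  })
  expect_equal(ov, brute)

  # bound: overlap cannot exceed the second-largest exceedance frequency
  ex <- sapply(list(m1, m2, m3), exceedance_frequency)
  second <- apply(ex, 1, function(v) sort(v, decreasing = TRUE)[2])
  expect_true(all(ov <= second + 1e-12))

  expect_error(overlap_frequency(list(m1)), "at least two")
})

test_that("bimodal primitives are flagged by multiple half-max runs", {
  uni <- make_primitive(list(list(center = 100, width = 30, amplitude = 1)))
  bi <- make_primitive(list(list(center = 40, width = 25, amplitude = 1),
                            list(center = 150, width = 25, amplitude = 0.9)))
  expect_identical(emgsynergy:::n_half_max_runs(uni), 1L)
  expect_identical(emgsynergy:::n_half_max_runs(bi), 2L)
  # wrap-around bump is a single circular run
  wrap <- make_primitive(list(list(center = 2, width = 30, amplitude = 1)))
  expect_identical(emgsynergy:::n_half_max_runs(wrap), 1L)
})
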