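# Repetition segmentation and the three per-repetition agreement metrics.

test_that("segment_repetitions cuts a five-cycle movement into five windows", {
  t <- seq(0, 15, by = 1 / 60)
  x <- 60 - 50 * cos(2 * pi * 5 * t / 15)  # five cycles starting at the minimum
  ang <- joint_angle_series(t, x, rep(0, length(t)), rep(0, length(t)))
  w <- segment_repetitions(ang, "flexion", expected = 5)
  expect_length(w, 5)
  lens <- vapply(w, function(z) z$end - z$start, numeric(1))
  expect_true(all(abs(lens - length(t) / 5) < 0.2 * length(t) / 5))
  # windows tile without overlap, ordered
  for (i in seq_len(4)) expect_identical(w[[i]]$end, w[[i + 1]]$start)
})

test_that("segment_repetitions rejects flat signals and warns on missing cycles", {
  t <- seq(0, 10, by = 1 / 60)
  flat <- joint_angle_series(t, rep(45, length(t)) + 0.01 * sin(t),
                             rep(0, length(t)), rep(0, length(t)))
  expect_error(segment_repetitions(flat, "flexion", expected = 5), "flat signal")
  x4 <- 60 - 50 * cos(2 * pi * 4 * t / 10)  # four full cycles
  ang <- joint_angle_series(t, x4, rep(0, length(t)), rep(0, length(t)))
  expect_warning(w <- segment_repetitions(ang, "flexion", expected = 5),
                 "found 4")
  expect_length(w, 4)
})

test_that("ROM error, RMSE and offset match their defining formulas", {
  expect_equal(rom_error(c(0, 50), c(5, 45)), 10)
  expect_equal(rom_error(1:10, 1:10), 0)
  expect_equal(rom_error(1:10, 1:10 + 3.2), 0)     # shift-invariant range
  expect_equal(rmse(c(0, 2), c(0, 0)), 1)
  expect_equal(rmse(1:10, 1:10 + 7.3), 0)          # demeaning removes offsets
  expect_equal(offset(rep(10, 4), rep(3, 4)), 7)
  expect_equal(offset(1:5, 1:5), 0)
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    a <- stats::rnorm(n, sd = 20); b <- stats::rnorm(n, sd = 20)
    expect_equal(rom_error(a, b), oracle_rom_error(a, b), tolerance = 1e-12)
    expect_equal(rmse(a, b), oracle_rmse(a, b), tolerance = 1e-12)
    expect_equal(offset(a, b), oracle_offset(a, b), tolerance = 1e-12)
  }
  expect_error(rom_error(numeric(0), 1:3), "empty")
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("metric invariances: shifts, swaps and signs", {
  set.seed(62)
  a <- stats::rnorm(40, 30, 15); b <- stats::rnorm(40, 25, 10)
  k <- 12.34
  expect_equal(rmse(a + k, b), rmse(a, b), tolerance = 1e-12)  # shift invariance
  expect_equal(rmse(a, b + k), rmse(a, b), tolerance = 1e-12)
  expect_equal(offset(a + k, b), offset(a, b) + k, tolerance = 1e-12)
  expect_equal(rom_error(a + k, b), rom_error(a, b), tolerance = 1e-12)
  # swapping reference and test negates the signed metrics, fixes RMSE
  expect_equal(rom_error(b, a), -rom_error(a, b), tolerance = 1e-12)
  expect_equal(offset(b, a), -offset(a, b), tolerance = 1e-12)
  expect_equal(rmse(b, a), rmse(a, b), tolerance = 1e-12)
})

test_that("offset estimate is unbiased under zero-mean noise", {
  set.seed(63)
  n <- 1e4
  a <- 40 + 10 * sin(seq_len(n) / 50)
  b <- a - 4 + stats::rnorm(n, 0, 2)
  se <- 2 / sqrt(n)
  expect_lt(abs(offset(a, b) - 4), 3 * se)
})

test_that("compute_metrics yields one record per window and axis", {
  prof <- zero_profile(seed = 64)
  tr <- generate_trial("flexion", prof)
  ref <- tr$truth_angles
  w <- segment_repetitions(ref, "flexion", expected = 5)
  m0 <- compute_metrics(ref, ref, w, meta = list(subject = "S01",
                                                 calibration = "MA",
                                                 task = "flexion"))
  expect_identical(nrow(m0), 15L)  # 5 windows x 3 axes
  expect_true(all(abs(c(m0$rom_error_deg, m0$rmse_deg, m0$offset_deg)) < 1e-12))
  expect_setequal(unique(m0$axis), c("flexion", "carrying", "pronation"))
  # constant +5 degree flexion bias: offset = -5 (reference minus test), RMSE = 0
  biased <- joint_angle_series(ref$t, ref$flexion_deg + 5, ref$carrying_deg,
                               ref$pronation_deg)
  m1 <- compute_metrics(ref, biased, w)
  fx <- m1[m1$axis == "flexion", ]
  expect_true(all(abs(fx$offset_deg + 5) < 1e-9))
  expect_true(all(fx$rmse_deg < 1e-9))
  expect_true(all(abs(fx$rom_error_deg) < 1e-9))
})
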