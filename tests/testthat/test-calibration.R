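# Hinge-axis estimation, axis translation and the three calibration methods.

test_that("hinge axis recovery: exact when noise-free, robust under noise", {
  rec <- make_hinge_rec(axis = c(0, 0, 1), sigma = 0)
  ax <- estimate_hinge_axis(rec)
  expect_equal(ax$axis, c(0, 0, 1), tolerance = 1e-12)
  expect_lt(ax$residual_ratio, 1e-12)

  set.seed(21)
  truth <- c(1, 2, -0.5); truth <- truth / sqrt(sum(truth^2))
  rec <- make_hinge_rec(axis = truth, sigma = 0.01, n = 500)
  ax <- estimate_hinge_axis(rec)
  expect_gt(abs(sum(ax$axis * truth)), 0.999)
  # oracle cross-check on the same noisy draw
  grid_axis <- oracle_axis_grid(rec$gyro)
  expect_lt(angle_between_deg(ax$axis, grid_axis), 3)
})

test_that("hinge axis estimator picks the dominant plane of a mixed movement", {
  # 90% / 10% energy split between two orthogonal axes
  t <- (0:999) / 100
  s1 <- sqrt(0.9) * sin(2 * pi * 0.5 * t)
  s2 <- sqrt(0.1) * sin(2 * pi * 1.1 * t)
  g <- outer(s1, c(0, 0, 1)) + outer(s2, c(1, 0, 0))
  rec <- inertial_recording(t, matrix(rep(quat_identity(), 1000), 1000, 4,
                                      byrow = TRUE), gyro = g)
  ax <- estimate_hinge_axis(rec)
  expect_lt(angle_between_deg(ax$axis, c(0, 0, 1)), 15)
  expect_lt(angle_between_deg(ax$axis, oracle_axis_grid(g)), 2)
  expect_gt(ax$residual_ratio, 0.01)
})

test_that("hinge axis error shrinks monotonically with gyro noise", {
  truth <- c(0, 0, 1)
  errs <- vapply(c(0.1, 0.05, 0.01, 0), function(sig) {
    set.seed(77)
    angle_between_deg(estimate_hinge_axis(make_hinge_rec(sigma = sig))$axis, truth)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_equal(errs[4], 0, tolerance = 1e-9)
})

test_that("hinge axis estimation rejects insufficient or degenerate motion", {
  rec <- make_hinge_rec(amp = 0.1)  # peak below the 0.3 rad/s motion floor
  expect_error(estimate_hinge_axis(rec), "insufficient motion")
  short <- make_hinge_rec(n = 50, rate = 100)
  expect_error(estimate_hinge_axis(short), "at least 2 s")
})

test_that("translate_axis re-expresses axes through the global frame", {
  q <- quat_from_axis_angle(c(1, 1, 0), 37)
  expect_equal(translate_axis(c(1, 0, 0), q, q), c(1, 0, 0), tolerance = 1e-12)
  qs <- quat_identity()
  qt <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), 90), qs)
  got <- translate_axis(c(1, 0, 0), qs, qt)
  oracle <- t(quat_to_matrix(qt)) %*% (quat_to_matrix(qs) %*% c(1, 0, 0))
  expect_equal(got, as.vector(oracle), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:100) {
    a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
    v <- translate_axis(a, random_unit_quat(), random_unit_quat())
    expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-12)
  }
})

test_that("N-pose calibration reduces to the mounting permutation for an ideal pose", {
  # all sensors at identity orientation; arm frames inherit the thorax frame
  t <- seq(0, 2, by = 0.02)
  idq <- matrix(rep(quat_identity(), length(t)), length(t), 4, byrow = TRUE)
  rec <- inertial_recording(t, idq)
  cal <- calibrate_npose(list(thorax = rec, upper_arm = rec, lower_arm = rec))
  expect_identical(cal$method, "NP")
  expect_equal(cal$q0_upper_arm, cal$q0_lower_arm, tolerance = 1e-12)
  # the frame is a fixed signed permutation: cranial<-up, forward<- -sensor_y
  frame <- cbind(c(0, -1, 0), c(0, 0, 1), c(-1, 0, 0))
  expect_lt(quat_angle_deg(cal$q0_upper_arm, quat_from_matrix(frame)), 1e-9)
})

test_that("N-pose calibration is invariant to a common heading rotation", {
  prof <- zero_profile(seed = 31)
  tr_np <- generate_trial("npose_static", prof)
  tr_fx <- generate_trial("flexion", prof)
  yaw <- quat_from_axis_angle(c(0, 0, 1), 30)
  spin <- function(rec) inertial_recording(rec$t,
                                           quat_multiply(matrix(yaw, 1), rec$q),
                                           gyro = rec$gyro, accel = rec$accel)
  cal0 <- calibrate_npose(tr_np$imu_streams)
  cal1 <- calibrate_npose(lapply(tr_np$imu_streams, spin))
  # q0 itself is heading-invariant here because the anatomical frame co-rotates
  expect_lt(quat_angle_deg(cal0$q0_upper_arm, cal1$q0_upper_arm), 1e-6)
  # and the downstream joint angles of a yawed trial are unchanged
  tr_fx_yawed <- tr_fx
  tr_fx_yawed$imu_streams <- lapply(tr_fx$imu_streams, spin)
  a0 <- trial_angles(tr_fx, cal0)
  a1 <- trial_angles(tr_fx_yawed, cal1)
  expect_lt(max_angle_err(a0, a1), 1e-6)
})

test_that("N-pose calibration on a perfect subject recovers task truth", {
  prof <- zero_profile(seed = 32)
  cal <- calibrate_npose(generate_trial("npose_static", prof)$imu_streams)
  tr <- generate_trial("flexion", prof)
  expect_lt(max_angle_err(trial_angles(tr, cal), tr$truth_angles), 1e-6)
})

test_that("N-pose stillness check rejects a moving subject", {
  prof <- zero_profile(seed = 33)
  tr <- generate_trial("flexion", prof)  # plenty of motion
  expect_error(calibrate_npose(tr$imu_streams), "stillness check failed")
})

test_that("functional calibration recovers mounting misalignments up to 20 degrees", {
  mis <- list(upper_arm = quat_from_axis_angle(c(1, 2, 3), 20),
              lower_arm = quat_from_axis_angle(c(-2, 1, 1), 15))
  prof <- zero_profile(seed = 41, mounting_misalignment = mis)
  fe <- generate_trial("fe_calibration", prof)
  ps <- generate_trial("ps_calibration", prof)
  cal <- calibrate_functional(fe$imu_streams$upper_arm, fe$imu_streams$lower_arm,
                              ps$imu_streams$lower_arm)
  # recovered flexion axis (segment z in sensor coords) vs ground truth
  truth_frame_ua <- t(quat_to_matrix(quat_multiply(
    quat_from_matrix(t(elbowcal:::.manual_alignment_frame())), mis$upper_arm)))
  got_z <- quat_to_matrix(cal$q0_upper_arm)[, 3]
  expect_lt(angle_between_deg(got_z, truth_frame_ua[, 3]), 0.1)
  # and the whole calibration closes the loop on a task trial
  tr <- generate_trial("drinking", prof)
  expect_lt(max_angle_err(trial_angles(tr, cal), tr$truth_angles), 1e-6)
})

test_that("functional calibration axis error stays below 2 degrees under gyro noise", {
  prof <- zero_profile(seed = 42, gyro_noise_sd = 0.02)
  fe <- generate_trial("fe_calibration", prof)
  ps <- generate_trial("ps_calibration", prof)
  cal <- calibrate_functional(fe$imu_streams$upper_arm, fe$imu_streams$lower_arm,
                              ps$imu_streams$lower_arm)
  nominal <- t(elbowcal:::.manual_alignment_frame())
  expect_lt(angle_between_deg(quat_to_matrix(cal$q0_upper_arm)[, 3],
                              t(nominal)[, 3]), 2)
  expect_lt(angle_between_deg(quat_to_matrix(cal$q0_lower_arm)[, 2],
                              t(nominal)[, 2]), 2)
})

test_that("functional calibration rejects a motionless pronation recording", {
  prof <- zero_profile(seed = 43)
  fe <- generate_trial("fe_calibration", prof)
  np <- generate_trial("npose_static", prof, duration_s = 10)
  expect_error(
    calibrate_functional(fe$imu_streams$upper_arm, fe$imu_streams$lower_arm,
                         np$imu_streams$lower_arm),
    "insufficient motion")
})

test_that("manual alignment is the fixed signed permutation, input-independent", {
  cal <- calibrate_manual()
  expect_identical(cal, calibrate_manual())
  r <- quat_to_matrix(cal$q0_upper_arm)
  expect_equal(r, cbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)), tolerance = 1e-12)
  expect_lt(abs(det(r) - 1), 1e-12)
  s2 <- sqrt(2) / 2
  expect_lt(min(max(abs(cal$q0_upper_arm - c(s2, 0, 0, -s2))),
                max(abs(cal$q0_upper_arm + c(s2, 0, 0, -s2)))), 1e-12)
  # perfectly mounted sensors: task angles equal ground truth
  prof <- zero_profile(seed = 44)
  tr <- generate_trial("pronation", prof)
  expect_lt(max_angle_err(trial_angles(tr, cal), tr$truth_angles), 1e-6)
})
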