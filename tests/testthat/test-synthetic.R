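# Virtual-subject simulator: trajectories, forward kinematics, corruption.

test_that("carrying angle follows the flexion-dependent profile", {
  prof <- subject_profile(carrying_angle_baseline_deg = 10,
                          carrying_angle_span_deg = 15,
                          carrying_shape = "linear", seed = 81)
  expect_equal(carrying_angle_of_flexion(0, prof), 10)
  expect_equal(carrying_angle_of_flexion(130, prof), -5)
  expect_equal(carrying_angle_of_flexion(150, prof), -5)  # saturates past 130
  expect_equal(carrying_angle_of_flexion(65, prof, shape = "sinusoidal"),
               10 - 15 / 2)  # half-sinusoid midpoint
  expect_error(carrying_angle_of_flexion(200, prof), "within")
  expect_error(subject_profile(carrying_angle_span_deg = 16), "\\[0, 15\\]")
})

test_that("task trajectories respect the protocol's waveform contracts", {
  prof <- zero_profile(seed = 82)
  fx <- generate_task_trajectory("flexion", reps = 5, profile = prof)$angles
  x <- fx$flexion_deg
  n_max <- sum(x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
                 x[2:(length(x) - 1)] > x[3:length(x)] & x[2:(length(x) - 1)] > 100)
  expect_identical(n_max, 5L)
  expect_lt(diff(range(fx$pronation_deg)), 5)
  fe <- generate_task_trajectory("fe_calibration", profile = prof)$angles
  expect_lt(abs(min(fe$flexion_deg) - 15), 2)
  expect_lt(abs(max(fe$flexion_deg) - 50), 2)
  np <- generate_task_trajectory("npose_static", profile = prof)$angles
  expect_lt(diff(range(np$flexion_deg)), 1e-12)
  expect_lt(diff(range(np$pronation_deg)), 1e-12)
  expect_error(generate_task_trajectory("jumping", profile = prof), "arg")
})

test_that("forward kinematics and elbow_angles are inverse maps", {
  prof <- subject_profile(seed = 83)
  traj <- generate_task_trajectory("box_off_shelf", profile = prof)
  zero <- joint_angle_series(traj$angles$t, 0 * traj$angles$t, 0 * traj$angles$t,
                             0 * traj$angles$t)
  fk0 <- forward_kinematics(zero, traj$trunk, prof)
  expect_lt(max(quat_angle_deg(fk0$upper_arm$q, fk0$lower_arm$q)), 1e-9)
  fk <- forward_kinematics(traj$angles, traj$trunk, prof, shoulder = traj$shoulder)
  back <- elbow_angles(fk$upper_arm, fk$lower_arm)
  expect_lt(max_angle_err(back, traj$angles), 1e-8)
})

test_that("virtual IMU corruption has the stated physical signatures", {
  # zero corruption: sensor equals segment composed with the nominal mounting
  prof0 <- zero_profile(seed = 84)
  tr <- generate_trial("flexion", prof0)
  nominal <- quat_from_matrix(t(elbowcal:::.manual_alignment_frame()))
  expect_lt(max(quat_angle_deg(
    tr$imu_streams$lower_arm$q,
    quat_multiply(tr$truth_orientations$lower_arm$q, nominal))), 1e-9)
  # static segment: accelerometer mean is sensor-frame gravity, norm ~ 9.81
  profn <- zero_profile(seed = 85, accel_noise_sd = 0.05)
  st <- generate_trial("npose_static", profn)$imu_streams$thorax
  amean <- colMeans(st$accel)
  pred <- quat_rotate(quat_inverse(st$q[1, ]), c(0, 0, 9.81))
  n <- nrow(st$accel)
  expect_lt(max(abs(amean - pred)), 3 * 0.05 / sqrt(n) * 3)
  expect_lt(abs(sqrt(sum(amean^2)) - 9.81), 0.05)
  # constant-rate rotation about z at 1 rad/s: finite-difference gyro recovers it
  t <- seq(0, 5, by = 0.01)
  half <- t / 2  # angle = 1 rad/s * t
  ser <- list(thorax = orientation_series(t, cbind(cos(half), 0, 0, sin(half))),
              upper_arm = orientation_series(t, cbind(cos(half), 0, 0, sin(half))),
              lower_arm = orientation_series(t, cbind(cos(half), 0, 0, sin(half))))
  prof_id <- zero_profile(seed = 86)
  prof_id$mounting_misalignment <- lapply(prof_id$mounting_misalignment,
                                          function(...) quat_from_matrix(
                                            elbowcal:::.manual_alignment_frame()))
  imu <- corrupt_to_imu(ser, prof_id)  # mounting cancels to identity
  gmean <- colMeans(imu$thorax$gyro)
  expect_equal(gmean, c(0, 0, 1), tolerance = 1e-6)
})

test_that("trial generation is deterministic and internally consistent", {
  prof <- subject_profile(mounting_error_deg = 5, npose_posture_error_deg = 4,
                          seed = 87)
  a <- generate_trial("drinking", prof)
  b <- generate_trial("drinking", prof)
  expect_identical(a, b)
  # invariant: truth angles equal elbow_angles of the truth orientations
  for (task in c("drinking", "npose_static", "ps_calibration")) {
    tr <- generate_trial(task, prof)
    got <- elbow_angles(tr$truth_orientations$upper_arm,
                        tr$truth_orientations$lower_arm)
    expect_lt(max_angle_err(got, tr$truth_angles), 1e-8)
  }
})

test_that("a study is reproducible and complete", {
  s1 <- generate_study(2, seed = 88, rate_hz = 30, task_duration_s = 6)
  s2 <- generate_study(2, seed = 88, rate_hz = 30, task_duration_s = 6)
  expect_identical(s1, s2)
  expect_length(s1$subjects, 2)
  expect_length(s1$subjects[[1]]$trials, 8)
  expect_false(identical(s1$subjects[[1]]$profile, s1$subjects[[2]]$profile))
})

test_that("manual alignment degrades gracefully with mounting misalignment", {
  errs <- vapply(c(0, 5, 10), function(m) {
    mis <- list(upper_arm = if (m == 0) quat_identity()
                else quat_from_axis_angle(c(1, -1, 2), m))
    prof <- zero_profile(seed = 89, mounting_misalignment = mis)
    tr <- generate_trial("flexion", prof)
    # MA with the true mounting recovers truth exactly
    if (m == 0) {
      cal_true <- calibrate_manual()
      expect_lt(max_angle_err(trial_angles(tr, cal_true), tr$truth_angles), 1e-6)
    }
    max_angle_err(trial_angles(tr, calibrate_manual()), tr$truth_angles)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 1e-6)
})

test_that("N-pose posture error hurts NP but not FC", {
  rmse_of <- function(np_err) {
    prof <- zero_profile(seed = 90, npose_posture_error_deg = np_err)
    trials <- lapply(setNames(nm = c("npose_static", "fe_calibration",
                                     "ps_calibration", "flexion")),
                     function(tk) generate_trial(tk, prof))
    calNP <- calibrate_npose(trials$npose_static$imu_streams)
    calFC <- calibrate_functional(trials$fe_calibration$imu_streams$upper_arm,
                                  trials$fe_calibration$imu_streams$lower_arm,
                                  trials$ps_calibration$imu_streams$lower_arm)
    ref <- trials$flexion$truth_angles
    w <- segment_repetitions(ref, "flexion", expected = 5)
    c(NP = mean(compute_metrics(ref, trial_angles(trials$flexion, calNP), w)$rmse_deg),
      FC = mean(compute_metrics(ref, trial_angles(trials$flexion, calFC), w)$rmse_deg))
  }
  r <- vapply(c(2, 5, 10), rmse_of, numeric(2))
  expect_true(all(diff(r["NP", ]) > 0))     # NP degrades monotonically
  expect_true(all(r["FC", ] < 1e-6))        # FC ignores the static pose
})
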