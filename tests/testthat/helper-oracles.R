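# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately avoid the code paths they check: rotation composition goes
# through explicit 3x3 matrices, the agreement metrics are re-transcribed
# literally, and hinge-axis recovery is cross-checked by brute-force energy
# maximization over a spherical grid.

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# rotation composition oracle via explicit matrices
oracle_compose <- function(a, b) quat_to_matrix(a) %*% quat_to_matrix(b)

# literal transcriptions of the three agreement metrics
oracle_rom_error <- function(opto, imu) {
  (max(opto) - min(opto)) - (max(imu) - min(imu))
}
oracle_rmse <- function(opto, imu) {
  n <- length(opto)
  sqrt(sum(((opto - mean(opto)) - (imu - mean(imu)))^2) / n)
}
oracle_offset <- function(opto, imu) mean(opto) - mean(imu)

# brute-force dominant rotation axis: maximize projected gyro energy over a
# Fibonacci sphere grid
oracle_axis_grid <- function(g, n_grid = 4000) {
  i <- seq_len(n_grid) - 0.5
  phi <- acos(1 - 2 * i / n_grid)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  energy <- colSums((g %*% t(dirs))^2)
  dirs[which.max(energy), ]
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# a synthetic single-hinge gyroscope recording
make_hinge_rec <- function(axis = c(0, 0, 1), sigma = 0, n = 1000, rate = 100,
                           amp = 1.2, freq = 0.5) {
  t <- (seq_len(n) - 1) / rate
  s <- amp * sin(2 * pi * freq * t)
  g <- outer(s, axis / sqrt(sum(axis^2)))
  if (sigma > 0) g <- g + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
  q <- matrix(rep(quat_identity(), n), n, 4, byrow = TRUE)
  inertial_recording(t, q, gyro = g)
}

# a corruption-free virtual subject (exact closed loop expected)
zero_profile <- function(seed = 1, ...) {
  args <- list(carrying_angle_baseline_deg = 0, carrying_angle_span_deg = 0,
               carrying_shape = "linear", mounting_error_deg = 0,
               npose_posture_error_deg = 0, gyro_noise_sd = 0,
               accel_noise_sd = 0, heading_drift_dps = 0, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(subject_profile, args)
}

# max absolute elbow-angle deviation between two series
max_angle_err <- function(a, b) {
  max(abs(a$flexion_deg - b$flexion_deg),
      abs(a$carrying_deg - b$carrying_deg),
      abs(a$pronation_deg - b$pronation_deg))
}

# calibrate + apply one method to one trial
trial_angles <- function(trial, cal) {
  ua <- apply_calibration(trial$imu_streams$upper_arm, cal$q0_upper_arm)
  la <- apply_calibration(trial$imu_streams$lower_arm, cal$q0_lower_arm)
  elbow_angles(ua, la)
}

# metric table for a synthetic records layout with planted effects
make_records <- function(n_subjects, cal_shift = c(NP = 0, FC = 0, MA = 0),
                         noise_sd = 0.5, subject_sd = 2, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                      calibration = names(cal_shift),
                      axis = c("flexion", "carrying", "pronation"),
                      task = c("flexion", "pronation", "drinking",
                               "box_off_shelf", "circles"),
                      repetition = 1L, stringsAsFactors = FALSE)
  intercept <- stats::rnorm(n_subjects, 0, subject_sd)
  names(intercept) <- sprintf("S%02d", seq_len(n_subjects))
  y <- intercept[grid$subject] + cal_shift[grid$calibration] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid$rom_error_deg <- grid$rmse_deg <- grid$offset_deg <- as.numeric(y)
  grid
}
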