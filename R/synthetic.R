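# Virtual-subject simulator: ground-truth upper-limb kinematics for the
# calibration recordings and the five movement tasks, plus corrupted virtual
# IMU streams (mounting misalignment, heading drift, sensor noise, imperfect
# static posture). Global frame: X forward, Y left, Z up; gravity is -Z.
# Segment frames follow the package convention (X forward, Y cranial,
# Z lateral), so the neutral standing segment orientation is a +90 degree
# rotation about global X.

.SENSORS <- c("thorax", "upper_arm", "lower_arm")
.TASKS <- c("flexion", "pronation", "drinking", "box_off_shelf", "circles",
            "npose_static", "fe_calibration", "ps_calibration")
.GRAVITY <- 9.81

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647)
  force(code)
}

.random_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

.random_small_rotation <- function(angle_deg) {
  if (angle_deg == 0) return(quat_identity())
  quat_from_axis_angle(.random_unit3(), angle_deg)
}

.neutral_segment_quat <- function() quat_from_axis_angle(c(1, 0, 0), 90)

#' Virtual subject profile
#'
#' Anatomy and corruption parameters of one simulated subject. Mounting
#' misalignments and N-pose posture deviations are drawn once from `seed`
#' (random axes at the requested magnitudes), so a profile fully determines
#' every trial generated from it.
#'
#' @param carrying_angle_baseline_deg Carrying angle at full elbow extension
#'   (degrees).
#' @param carrying_angle_span_deg How much the carrying angle decreases from
#'   full extension to 130 degrees of flexion; must lie in `[0, 15]`.
#' @param carrying_shape `"linear"` or `"sinusoidal"` flexion dependence.
#' @param mounting_error_deg Magnitude (degrees) of the sensor mounting
#'   misalignment away from the nominal manual-alignment placement; scalar
#'   or named vector over thorax/upper_arm/lower_arm.
#' @param npose_posture_error_deg Magnitude (degrees) of the deviation from
#'   a perfect N-pose held during the static calibration (shoulder and elbow
#'   components drawn from it).
#' @param gyro_noise_sd Gyroscope noise s.d. (rad/s).
#' @param accel_noise_sd Accelerometer noise s.d. (m/s^2).
#' @param heading_drift_dps Heading drift rate about the vertical
#'   (degrees/s) of the simulated orientation estimate.
#' @param seed Integer seed for all subject-level draws.
#' @param mounting_misalignment Optional named list of unit quaternions
#'   overriding the drawn misalignments (composed after the nominal
#'   mounting rotation).
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(carrying_angle_baseline_deg = 12,
                            carrying_angle_span_deg = 8,
                            carrying_shape = c("sinusoidal", "linear"),
                            mounting_error_deg = 0,
                            npose_posture_error_deg = 0,
                            gyro_noise_sd = 0.01,
                            accel_noise_sd = 0.05,
                            heading_drift_dps = 0.05,
                            seed = 1L,
                            mounting_misalignment = NULL) {
  carrying_shape <- match.arg(carrying_shape)
  if (!is.finite(carrying_angle_span_deg) ||
      carrying_angle_span_deg < 0 || carrying_angle_span_deg > 15)
    stop("carrying_angle_span_deg must lie in [0, 15]")
  if (gyro_noise_sd < 0 || accel_noise_sd < 0 || heading_drift_dps < 0)
    stop("noise and drift parameters must be non-negative")
  merr <- rep_len(mounting_error_deg, 3L)
  if (!is.null(names(mounting_error_deg))) {
    merr <- mounting_error_deg[.SENSORS]
    if (any(is.na(merr))) stop("named mounting_error_deg must cover ", paste(.SENSORS, collapse = ", "))
  }
  names(merr) <- .SENSORS
  drawn <- .with_seed(seed * 7919 + 1, {
    mis <- lapply(merr, .random_small_rotation)
    shoulder_dev <- .random_small_rotation(npose_posture_error_deg)
    elbow_dev <- npose_posture_error_deg * .random_unit3()
    list(mis = mis, shoulder_dev = shoulder_dev, elbow_dev = elbow_dev)
  })
  mis <- drawn$mis
  if (!is.null(mounting_misalignment)) {
    for (s in names(mounting_misalignment)) {
      if (!s %in% .SENSORS) stop("unknown sensor in mounting_misalignment: ", s)
      mis[[s]] <- quat_normalize(mounting_misalignment[[s]])
    }
  }
  structure(list(
    carrying_angle_baseline_deg = carrying_angle_baseline_deg,
    carrying_angle_span_deg = carrying_angle_span_deg,
    carrying_shape = carrying_shape,
    mounting_error_deg = merr,
    mounting_misalignment = mis,
    npose_posture_error_deg = npose_posture_error_deg,
    npose_shoulder_dev = drawn$shoulder_dev,
    npose_elbow_dev_deg = drawn$elbow_dev,
    gyro_noise_sd = gyro_noise_sd,
    accel_noise_sd = accel_noise_sd,
    heading_drift_dps = heading_drift_dps,
    seed = as.integer(seed)), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> carrying %.1f-%.1f deg (%s); mount err %s deg; npose err %.1f deg;\n  gyro sd %.3g rad/s, accel sd %.3g m/s^2, drift %.3g deg/s, seed %d\n",
    x$carrying_angle_baseline_deg,
    x$carrying_angle_baseline_deg - x$carrying_angle_span_deg, x$carrying_shape,
    paste(sprintf("%.1f", x$mounting_error_deg), collapse = "/"),
    x$npose_posture_error_deg, x$gyro_noise_sd, x$accel_noise_sd,
    x$heading_drift_dps, x$seed))
  invisible(x)
}

#' Carrying angle as a function of elbow flexion
#'
#' Baseline value at full extension, decreasing by the subject's span at 130
#' degrees of flexion, with either a linear or a half-sinusoid profile
#' (constant beyond 130 degrees).
#'
#' @param flexion_deg Flexion angle(s) in degrees, within `[0, 150]`.
#' @param profile [subject_profile()].
#' @param shape Override of the profile's shape.
#' @return Carrying angle(s) in degrees.
#' @export
carrying_angle_of_flexion <- function(flexion_deg, profile, shape = profile$carrying_shape) {
  if (any(flexion_deg < -1e-9 | flexion_deg > 150))
    stop("flexion must lie within [0, 150] degrees")
  f <- pmin(pmax(flexion_deg, 0), 130) / 130
  frac <- switch(match.arg(shape, c("sinusoidal", "linear")),
                 linear = f,
                 sinusoidal = (1 - cos(pi * f)) / 2)
  profile$carrying_angle_baseline_deg - profile$carrying_angle_span_deg * frac
}

# raised-cosine cycle phase in [0, 1], starting at 0
.phase <- function(t, reps, lag = 0) (1 - cos(2 * pi * reps * t / max(t) - lag)) / 2

#' Ground-truth joint angle trajectory and trunk motion for one task
#'
#' Smooth (C1) raised-cosine / sinusoid waveforms covering the protocol's
#' movement tasks and calibration recordings: full-range flexion cycles
#' (10-130 degrees), pronation cycles (+/-80 degrees at 90 degrees flexion),
#' three multi-joint tasks mixing both axes with gentle trunk motion, the
#' static N-pose (with the profile's posture deviation), the 15-50 degree
#' flexion/extension calibration movement and the full-range pronation
#' calibration movement. The carrying angle follows
#' [carrying_angle_of_flexion()].
#'
#' @param task One of `r paste0('"', .TASKS, '"', collapse = ", ")`.
#' @param duration_s Trial length in seconds (defaults: 3 s static, 10 s
#'   calibration movements, 15 s tasks).
#' @param reps Number of movement repetitions (default 5).
#' @param rate_hz Sampling rate (default 60).
#' @param profile [subject_profile()].
#' @return List with `angles` ([joint_angle_series()]), `trunk`
#'   ([orientation_series()]) and `shoulder` (fixed trunk->upper-arm
#'   quaternion).
#' @export
generate_task_trajectory <- function(task, duration_s = NULL, reps = 5,
                                     rate_hz = 60, profile = subject_profile()) {
  task <- match.arg(task, .TASKS)
  if (reps < 1) stop("reps must be at least 1")
  if (is.null(duration_s))
    duration_s <- switch(task, npose_static = 3,
                         fe_calibration = , ps_calibration = 10, 15)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  n <- length(t)
  ph <- .phase(t, reps)
  ph2 <- .phase(t, reps, lag = pi / 2)
  w <- 2 * pi * reps * t / duration_s
  zero <- rep(0, n)
  pitch <- zero; yaw <- zero
  shoulder <- quat_identity()
  carry_extra <- zero
  if (task == "flexion") {
    flex <- 10 + 120 * ph; pron <- zero
  } else if (task == "pronation") {
    flex <- rep(90, n); pron <- 80 * sin(w)
  } else if (task == "drinking") {
    flex <- 15 + 95 * ph; pron <- 40 * ph2
    pitch <- 5 * ph; shoulder <- quat_from_zxy(30, 0, 0)
  } else if (task == "box_off_shelf") {
    flex <- 20 + 80 * ph; pron <- -20 + 40 * ph2
    pitch <- 8 * ph; shoulder <- quat_from_zxy(35, 0, 0)
  } else if (task == "circles") {
    flex <- 50 + 20 * sin(w); pron <- 10 + 30 * cos(w)
    yaw <- 5 * sin(2 * pi * t / duration_s); shoulder <- quat_from_zxy(45, 0, 0)
  } else if (task == "npose_static") {
    dev <- profile$npose_elbow_dev_deg
    flex <- rep(abs(dev[1]), n); pron <- rep(dev[3], n)
    carry_extra <- rep(dev[2], n)
    shoulder <- profile$npose_shoulder_dev
  } else if (task == "fe_calibration") {
    flex <- 15 + 35 * ph; pron <- zero
  } else { # ps_calibration
    flex <- rep(90, n); pron <- 80 * sin(w)
  }
  carry <- carrying_angle_of_flexion(flex, profile) + carry_extra
  qn <- .neutral_segment_quat()
  qp <- cbind(cos(pitch * pi / 360), 0, sin(pitch * pi / 360), 0)
  qy <- cbind(cos(yaw * pi / 360), 0, 0, sin(yaw * pi / 360))
  trunk_q <- quat_multiply(quat_multiply(qy, qp), matrix(qn, 1))
  list(angles = joint_angle_series(t, flex, carry, pron),
       trunk = orientation_series(t, trunk_q),
       shoulder = shoulder)
}

#' Forward kinematics: segment orientations from joint angles
#'
#' Upper-arm orientation is the trunk orientation composed with the fixed
#' shoulder pose; the forearm adds the elbow rotation composed from the
#' ZXY joint angles. By construction, [elbow_angles()] of the output
#' reproduces the input angles.
#'
#' @param angles [joint_angle_series()] of ground-truth elbow angles.
#' @param trunk [orientation_series()] of the trunk segment.
#' @param profile [subject_profile()] (carried through for provenance).
#' @param shoulder Fixed trunk->upper-arm quaternion (default identity).
#' @return Named list of [orientation_series()]: `thorax`, `upper_arm`,
#'   `lower_arm`.
#' @export
forward_kinematics <- function(angles, trunk, profile = subject_profile(),
                               shoulder = quat_identity()) {
  if (length(angles$t) != length(trunk$t) || max(abs(angles$t - trunk$t)) > 1e-9)
    stop("angles and trunk series are not time-aligned")
  q_ua <- quat_multiply(trunk$q, matrix(shoulder, 1))
  q_elbow <- quat_from_zxy(angles$flexion_deg, angles$carrying_deg, angles$pronation_deg)
  q_la <- quat_multiply(q_ua, q_elbow)
  list(thorax = trunk,
       upper_arm = orientation_series(angles$t, q_ua),
       lower_arm = orientation_series(angles$t, q_la))
}

# body-frame angular velocity (rad/s) by central differences of a
# quaternion series
.body_rates <- function(t, qm) {
  n <- nrow(qm)
  ia <- c(1L, 1:(n - 2L), n - 1L)
  ib <- c(2L, 3:n, n)
  d <- quat_multiply(quat_inverse(qm[ia, , drop = FALSE]), qm[ib, , drop = FALSE])
  s <- sign(d[, 1]); s[s == 0] <- 1
  d <- d * s
  vn <- sqrt(rowSums(d[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, d[, 1])
  scale <- ifelse(vn > 1e-12, ang / vn, 2)  # small-angle: 2*v approximates angle*axis
  (d[, 2:4, drop = FALSE] * scale) / (t[ib] - t[ia])
}

#' Corrupt ground-truth segment orientations into virtual IMU streams
#'
#' Sensor orientation = segment orientation composed with the nominal
#' mounting rotation and the profile's per-sensor misalignment, then
#' perturbed by a heading random walk about the vertical at the profile's
#' drift rate. The gyroscope is the finite-difference body angular velocity
#' of the corrupted orientation plus Gaussian noise; the accelerometer is
#' gravity resolved in the corrupted sensor frame plus Gaussian noise
#' (linear acceleration omitted). Draws come from the current RNG state;
#' seed upstream (see [generate_trial()]) for reproducibility.
#'
#' @param truth Named list of segment [orientation_series()] (`thorax`,
#'   `upper_arm`, `lower_arm`), e.g. from [forward_kinematics()].
#' @param profile [subject_profile()].
#' @return Named list of [inertial_recording()] per sensor.
#' @export
corrupt_to_imu <- function(truth, profile) {
  nominal <- quat_from_matrix(t(.manual_alignment_frame()))
  out <- list()
  for (s in .SENSORS) {
    seg <- truth[[s]]
    if (is.null(seg)) stop("truth is missing segment ", s)
    t <- seg$t; n <- length(t)
    q_mount <- quat_multiply(nominal, profile$mounting_misalignment[[s]])
    q_s <- quat_multiply(seg$q, matrix(q_mount, 1))
    if (profile$heading_drift_dps > 0) {
      dt <- c(diff(t), 0)
      dir <- sample(c(-1, 1), 1L)
      psi <- dir * profile$heading_drift_dps * t +
        cumsum(stats::rnorm(n, 0, profile$heading_drift_dps * dt))
      half <- psi * pi / 360
      q_s <- quat_multiply(cbind(cos(half), 0, 0, sin(half)), q_s)
    }
    gyro <- .body_rates(t, q_s)
    if (profile$gyro_noise_sd > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, profile$gyro_noise_sd), n, 3)
    accel <- quat_rotate(quat_inverse(q_s), matrix(c(0, 0, .GRAVITY), 1)[rep(1, n), ])
    if (profile$accel_noise_sd > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, 0, profile$accel_noise_sd), n, 3)
    out[[s]] <- inertial_recording(t, q_s, gyro = gyro, accel = accel)
  }
  out
}

#' Generate one complete synthetic trial
#'
#' Trajectory, ground-truth segment orientations and corrupted IMU streams
#' for one task, deterministically seeded from the profile seed and the
#' task, so any trial can be regenerated in isolation.
#'
#' @inheritParams generate_task_trajectory
#' @return Object of class `synthetic_trial`: list with `task`,
#'   `truth_angles`, `truth_orientations`, `imu_streams`, `profile`.
#' @export
generate_trial <- function(task, profile = subject_profile(), duration_s = NULL,
                           reps = 5, rate_hz = 60) {
  task <- match.arg(task, .TASKS)
  seed <- (abs(profile$seed) %% 20000000L) * 100L + match(task, .TASKS)
  .with_seed(seed, {
    traj <- generate_task_trajectory(task, duration_s = duration_s, reps = reps,
                                     rate_hz = rate_hz, profile = profile)
    truth <- forward_kinematics(traj$angles, traj$trunk, profile,
                                shoulder = traj$shoulder)
    imu <- corrupt_to_imu(truth, profile)
    structure(list(task = task, truth_angles = traj$angles,
                   truth_orientations = truth, imu_streams = imu,
                   profile = profile), class = "synthetic_trial")
  })
}

#' Parameter ranges for a simulated study population
#'
#' Ranges from which [generate_study()] draws each subject's profile.
#' Defaults emulate a healthy adult cohort wearing consumer-grade IMUs:
#' carrying angle 8-16 degrees at extension with a 5-12 degree flexion
#' dependence, a few degrees of sensor placement error and of N-pose
#' posture deviation, and modest sensor noise and heading drift.
#'
#' @param carrying_baseline_deg,carrying_span_deg,mounting_error_deg,npose_error_deg
#'   Two-element min/max ranges (degrees).
#' @param shapes Candidate carrying-angle shapes.
#' @param gyro_noise_sd,accel_noise_sd,heading_drift_dps Fixed noise levels.
#' @return Named list of ranges.
#' @export
study_profile_ranges <- function(carrying_baseline_deg = c(8, 16),
                                 carrying_span_deg = c(5, 12),
                                 shapes = c("linear", "sinusoidal"),
                                 mounting_error_deg = c(2, 8),
                                 npose_error_deg = c(2, 8),
                                 gyro_noise_sd = 0.01,
                                 accel_noise_sd = 0.05,
                                 heading_drift_dps = 0.05) {
  list(carrying_baseline_deg = carrying_baseline_deg,
       carrying_span_deg = carrying_span_deg, shapes = shapes,
       mounting_error_deg = mounting_error_deg,
       npose_error_deg = npose_error_deg, gyro_noise_sd = gyro_noise_sd,
       accel_noise_sd = accel_noise_sd, heading_drift_dps = heading_drift_dps)
}

#' Corruption-free parameter ranges
#'
#' Every anatomical offset, placement error, posture deviation, noise level
#' and drift rate set to zero: the closed-loop configuration in which all
#' three calibrations must recover ground truth exactly.
#'
#' @return Named list of ranges, as [study_profile_ranges()].
#' @export
zero_corruption_ranges <- function() {
  study_profile_ranges(carrying_baseline_deg = c(0, 0),
                       carrying_span_deg = c(0, 0), shapes = "linear",
                       mounting_error_deg = c(0, 0), npose_error_deg = c(0, 0),
                       gyro_noise_sd = 0, accel_noise_sd = 0,
                       heading_drift_dps = 0)
}

.draw_profile <- function(ranges, seed) {
  .with_seed(seed * 6271 + 17, {
    r <- function(x) if (length(x) == 2L) stats::runif(1, x[1], x[2]) else x[1]
    shape <- if (length(ranges$shapes) > 1L) sample(ranges$shapes, 1L) else ranges$shapes
    subject_profile(
      carrying_angle_baseline_deg = r(ranges$carrying_baseline_deg),
      carrying_angle_span_deg = r(ranges$carrying_span_deg),
      carrying_shape = shape,
      mounting_error_deg = r(ranges$mounting_error_deg),
      npose_posture_error_deg = r(ranges$npose_error_deg),
      gyro_noise_sd = ranges$gyro_noise_sd,
      accel_noise_sd = ranges$accel_noise_sd,
      heading_drift_dps = ranges$heading_drift_dps,
      seed = seed)
  })
}

#' Generate a full synthetic study
#'
#' One profile per subject drawn from the configured ranges, and all eight
#' trial types (five tasks plus the three calibration recordings) per
#' subject. Deterministic given the seed.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param seed Integer master seed.
#' @param ranges Profile ranges, see [study_profile_ranges()].
#' @param rate_hz Sampling rate (default 60).
#' @param reps Repetitions per movement trial (default 5).
#' @param task_duration_s Movement-task length in seconds (default 15).
#' @return Object of class `synthetic_study`: list of subjects, each with
#'   `id`, `profile` and a named list `trials` over all eight tasks.
#' @export
generate_study <- function(n_subjects = 13, seed = 1,
                           ranges = study_profile_ranges(), rate_hz = 60,
                           reps = 5, task_duration_s = 15) {
  if (n_subjects < 1) stop("need at least one subject")
  subjects <- lapply(seq_len(n_subjects), function(s) {
    prof <- .draw_profile(ranges, seed = (abs(seed) %% 1000000L) * 1000L + s)
    trials <- lapply(.TASKS, function(task) {
      dur <- if (task %in% c("flexion", "pronation", "drinking", "box_off_shelf",
                             "circles")) task_duration_s else NULL
      generate_trial(task, prof, duration_s = dur, reps = reps, rate_hz = rate_hz)
    })
    names(trials) <- .TASKS
    list(id = sprintf("S%02d", s), profile = prof, trials = trials)
  })
  structure(list(subjects = subjects, seed = seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects x %d trials (seed %s)\n",
              length(x$subjects), length(x$subjects[[1]]$trials),
              format(x$seed)))
  invisible(x)
}
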