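# Sensor-to-segment calibration. Each method produces, per arm segment, the
# calibration quaternion q0 (segment -> sensor, i.e. the fixed rotation that
# right-multiplies the runtime global<-sensor orientation to give the
# global<-segment orientation). Segment frame convention, neutral posture:
# X forward, Y cranial (longitudinal, proximal), Z lateral (flexion axis,
# pointing right for a right arm).

# Sensor mounting convention (manual-alignment assumption): segment axes
# expressed in sensor coordinates are X = -sensor y, Y = +sensor x,
# Z = +sensor z. Columns of this matrix are segment x, y, z in the sensor
# frame, so the matrix itself is the segment->sensor rotation.
.manual_alignment_frame <- function() {
  cbind(x = c(0, -1, 0), y = c(1, 0, 0), z = c(0, 0, 1))
}

.window_middle <- function(n, frac = 0.5) {
  k <- max(2L, floor(n * frac))
  start <- max(1L, floor((n - k) / 2) + 1L)
  seq.int(start, min(n, start + k - 1L))
}

#' Calibration result container
#'
#' @param method One of `"NP"`, `"FC"`, `"MA"`.
#' @param q0_upper_arm,q0_lower_arm Unit quaternions (segment -> sensor).
#' @param diagnostics Named list of scalar diagnostics.
#' @return Object of class `calibration_result`.
#' @export
calibration_result <- function(method, q0_upper_arm, q0_lower_arm,
                               diagnostics = list()) {
  method <- match.arg(method, c("NP", "FC", "MA"))
  structure(list(method = method,
                 q0_upper_arm = quat_normalize(q0_upper_arm),
                 q0_lower_arm = quat_normalize(q0_lower_arm),
                 diagnostics = diagnostics),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> method %s\n", x$method))
  cat("  q0 upper arm:", sprintf("% .4f", x$q0_upper_arm), "\n")
  cat("  q0 lower arm:", sprintf("% .4f", x$q0_lower_arm), "\n")
  if (length(x$diagnostics)) {
    d <- unlist(x$diagnostics)
    cat("  diagnostics:", paste(sprintf("%s=%.4g", names(d), d), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate a hinge rotation axis from gyroscope data
#'
#' The dominant rotation direction of an oscillatory single-axis movement,
#' taken as the first right-singular vector of the raw (uncentered) n x 3
#' gyroscope sample matrix. Because hinge angular velocity reverses sign
#' across movement cycles the raw second-moment direction is the hinge axis;
#' no mean-centering is needed. The sign is disambiguated so that the first
#' movement lobe projects positively on the axis, which makes flexion (or
#' pronation) positive when the calibration movement starts with it.
#'
#' @param rec [inertial_recording()] with a `gyro` stream covering at least
#'   2 s of oscillatory rotation.
#' @param min_peak_rad_s Minimum peak angular speed (rad/s) counted as
#'   motion; default 0.3.
#' @return Object of class `joint_axis_estimate`: list with unit 3-vector
#'   `axis` (sensor frame), `residual_ratio` (fraction of gyroscope energy
#'   off-axis, in `[0, 1]`) and `sign_convention`.
#' @export
estimate_hinge_axis <- function(rec, min_peak_rad_s = 0.3) {
  if (!inherits(rec, "inertial_recording") || is.null(rec$gyro))
    stop("estimate_hinge_axis needs an inertial_recording with a gyro stream")
  if (diff(range(rec$t)) < 2)
    stop("insufficient data: need at least 2 s of calibration movement")
  g <- rec$gyro
  speed <- sqrt(rowSums(g^2))
  if (max(speed) < min_peak_rad_s)
    stop(sprintf("insufficient motion: peak angular speed %.3f rad/s is below %.2f rad/s",
                 max(speed), min_peak_rad_s))
  sv <- svd(g, nu = 0)
  if (sv$d[1] < 1e-12) stop("rank-deficient gyroscope data")
  axis <- sv$v[, 1]
  energy <- sum(sv$d^2)
  residual <- 1 - sv$d[1]^2 / energy
  # sign: first lobe of the projected angular velocity must be positive
  p <- as.vector(g %*% axis)
  i0 <- which(abs(p) > 0.5 * max(abs(p)))[1]
  if (p[i0] < 0) axis <- -axis
  structure(list(axis = axis, residual_ratio = residual,
                 sign_convention = "positive-first-lobe"),
            class = "joint_axis_estimate")
}

#' Re-express an axis measured in one sensor frame in another sensor frame
#'
#' Rotates the axis from the source sensor frame into the global frame and
#' back down into the target sensor frame, using the two sensors'
#' orientations at the same instant (or window average).
#'
#' @param axis_in_source Unit 3-vector in the source sensor frame.
#' @param q_source,q_target Unit quaternions (global <- sensor) for the
#'   source and target sensors at the same time.
#' @return Unit 3-vector in the target sensor frame.
#' @export
translate_axis <- function(axis_in_source, q_source, q_target) {
  a <- .unit3(axis_in_source, "axis")
  v <- quat_rotate(quat_inverse(q_target), quat_rotate(q_source, a))
  v / sqrt(sum(v^2))
}

#' N-pose (static) calibration
#'
#' The subject stands still with straight arms alongside the body. The
#' thorax anatomical frame is built from the gravity line (cranial axis) and
#' the thorax sensor's nominal forward direction orthogonalized against it;
#' both arm segment frames are then set equal to this thorax frame at the
#' calibration instant, so the arm calibrations depend only on the trunk
#' sensor's orientation and gravity.
#'
#' @param static Named list with elements `thorax`, `upper_arm`, `lower_arm`,
#'   each an [inertial_recording()] (or [orientation_series()]; accelerometer
#'   streams, when present, feed a gravity-consistency diagnostic) of at
#'   least 1 s of standing still.
#' @param gravity_up Unit 3-vector, global direction opposite gravity
#'   (default `c(0, 0, 1)`).
#' @param forward_axis_sensor Nominal forward direction of the thorax sensor
#'   in its own frame; default `c(0, -1, 0)` per the mounting convention.
#' @param max_still_deg Maximum orientation spread (degrees) tolerated over
#'   the analysis window before the stillness check fails (default 2).
#' @return [calibration_result()] with method `"NP"`. Diagnostics include the
#'   per-segment orientation spread and, when accelerometer data are
#'   available, the angle between measured and orientation-predicted gravity
#'   (a warning is raised beyond 10 degrees).
#' @export
calibrate_npose <- function(static, gravity_up = c(0, 0, 1),
                            forward_axis_sensor = c(0, -1, 0),
                            max_still_deg = 2) {
  need <- c("thorax", "upper_arm", "lower_arm")
  if (!all(need %in% names(static)))
    stop("static must be a named list with thorax, upper_arm and lower_arm recordings")
  gravity_up <- .unit3(gravity_up, "gravity_up")
  qmean <- list(); diag <- list()
  for (seg in need) {
    rec <- static[[seg]]
    if (diff(range(rec$t)) < 1) stop("static recording for ", seg, " is shorter than 1 s")
    win <- .window_middle(length(rec$t))
    qw <- rec$q[win, , drop = FALSE]
    qm <- quat_mean(qw)
    spread <- max(quat_angle_deg(qw, qm))
    if (spread > max_still_deg)
      stop(sprintf("stillness check failed for %s: orientation spread %.2f deg exceeds %g deg",
                   seg, spread, max_still_deg))
    diag[[paste0("still_spread_", seg, "_deg")]] <- spread
    if (!is.null(rec$accel)) {
      amean <- colMeans(rec$accel[win, , drop = FALSE])
      an <- sqrt(sum(amean^2))
      if (an > 1e-6) {
        pred <- quat_rotate(quat_inverse(qm), gravity_up)
        dev <- acos(pmin(1, sum(amean / an * pred))) * 180 / pi
        diag[[paste0("gravity_dev_", seg, "_deg")]] <- dev
        if (dev > 10)
          warning(sprintf("N-pose gravity check: %s accelerometer deviates %.1f deg from the orientation-predicted gravity line",
                          seg, dev))
      }
    }
    qmean[[seg]] <- qm
  }
  forward_global <- quat_rotate(qmean$thorax, .unit3(forward_axis_sensor, "forward axis"))
  frame <- frame_from_axes(gravity_up, forward_global, roles = c("y", "x"))
  q_frame <- quat_from_matrix(frame)
  calibration_result(
    "NP",
    q0_upper_arm = quat_multiply(quat_inverse(qmean$upper_arm), q_frame),
    q0_lower_arm = quat_multiply(quat_inverse(qmean$lower_arm), q_frame),
    diagnostics = diag)
}

#' Functional calibration from prescribed single-axis movements
#'
#' Upper arm: the elbow flexion axis is estimated from the lower-arm
#' gyroscope during the flexion/extension calibration movement, translated
#' into the upper-arm sensor frame through the (window-averaged) sensor
#' orientations, and used as the lateral (Z) axis; the upper-arm
#' accelerometer mean during the same still-upper-arm movement provides the
#' cranial (Y) direction. Lower arm: the pronation axis estimated from the
#' lower-arm gyroscope during the pronation movement is the longitudinal
#' (Y) axis; with the elbow flexed at 90 degrees the global vertical, mapped
#' into the lower-arm sensor frame at the window-mean orientation, lies
#' along the segment's forward (X) axis and serves as the secondary
#' direction.
#'
#' @param fe_ua Upper-arm [inertial_recording()] of the flexion/extension
#'   calibration movement (accelerometer required).
#' @param fe_la Lower-arm recording of the same movement (gyro required).
#' @param ps_la Lower-arm recording of the pronation/supination movement
#'   performed with the elbow flexed at about 90 degrees (gyro required).
#' @param max_residual_ratio Reject axis fits with more than this fraction
#'   of gyroscope energy off-axis (default 0.5).
#' @param gravity_up Global up direction (default `c(0, 0, 1)`).
#' @return [calibration_result()] with method `"FC"`; diagnostics carry the
#'   two axis-fit residual ratios.
#' @export
calibrate_functional <- function(fe_ua, fe_la, ps_la,
                                 max_residual_ratio = 0.5,
                                 gravity_up = c(0, 0, 1)) {
  ax_fe <- estimate_hinge_axis(fe_la)
  if (ax_fe$residual_ratio > max_residual_ratio)
    stop(sprintf("flexion calibration movement is not single-plane: residual ratio %.2f",
                 ax_fe$residual_ratio))
  q_la_fe <- quat_mean(fe_la$q)
  q_ua_fe <- quat_mean(fe_ua$q)
  axis_ua <- translate_axis(ax_fe$axis, q_la_fe, q_ua_fe)
  if (is.null(fe_ua$accel)) stop("upper-arm flexion recording needs accelerometer data")
  cranial_ua <- colMeans(fe_ua$accel)
  frame_ua <- frame_from_axes(axis_ua, cranial_ua, roles = c("z", "y"))

  ax_ps <- estimate_hinge_axis(ps_la)
  if (ax_ps$residual_ratio > max_residual_ratio)
    stop(sprintf("pronation calibration movement is not single-plane: residual ratio %.2f",
                 ax_ps$residual_ratio))
  vert_la <- quat_rotate(quat_inverse(quat_mean(ps_la$q)), .unit3(gravity_up, "gravity_up"))
  frame_la <- frame_from_axes(ax_ps$axis, vert_la, roles = c("y", "x"))

  calibration_result(
    "FC",
    q0_upper_arm = quat_from_matrix(frame_ua),
    q0_lower_arm = quat_from_matrix(frame_la),
    diagnostics = list(fe_residual_ratio = ax_fe$residual_ratio,
                       ps_residual_ratio = ax_ps$residual_ratio))
}

#' Manual-alignment calibration
#'
#' Assumes each sensor was physically mounted so that its axes coincide with
#' the anatomical axes: segment forward = -sensor y, cranial = +sensor x,
#' lateral = +sensor z. The calibration quaternion is the corresponding
#' fixed axis permutation, identical for both segments and independent of
#' any recording.
#'
#' @return [calibration_result()] with method `"MA"`.
#' @export
calibrate_manual <- function() {
  q0 <- quat_from_matrix(.manual_alignment_frame())
  calibration_result("MA", q0_upper_arm = q0, q0_lower_arm = q0)
}
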