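# Time-series containers. An orientation_series carries timestamps plus unit
# quaternions (global <- sensor or global <- segment); an inertial_recording
# adds synchronized gyroscope (rad/s) and accelerometer (m/s^2) samples in
# the sensor frame; a joint_angle_series carries the three elbow angles.

.check_time <- function(t, max_jitter = 0.2) {
  if (length(t) < 2L) stop("series needs at least 2 samples")
  if (!all(is.finite(t))) stop("non-finite timestamps")
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing (first violation at sample ",
         which(dt <= 0)[1] + 1L, ")")
  }
  md <- stats::median(dt)
  if (max(abs(dt - md)) > max_jitter * md)
    stop(sprintf("sampling interval jitter exceeds %.0f%% of the median interval",
                 100 * max_jitter))
  invisible(t)
}

.check_quat_rows <- function(q, tol_norm = 0.01) {
  if (!is.matrix(q) || ncol(q) != 4L) stop("q must be an n x 4 quaternion matrix")
  bad <- which(!apply(is.finite(q), 1L, all))
  if (length(bad)) stop("non-finite quaternion at row(s) ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  n <- sqrt(rowSums(q^2))
  off <- which(abs(n - 1) > tol_norm)
  if (length(off)) {
    stop(sprintf("quaternion norm deviates more than %.0f%% from 1 at row(s) %s",
                 100 * tol_norm, paste(utils::head(off, 5L), collapse = ", ")))
  }
  q / n
}

#' Orientation time series
#'
#' @param t Timestamps in seconds, strictly increasing, near-constant rate.
#' @param q n x 4 matrix of unit quaternions (scalar first), one per sample.
#' @return Object of class `orientation_series`: list with `t` and `q`.
#' @export
orientation_series <- function(t, q) {
  .check_time(t)
  q <- .check_quat_rows(q)
  if (length(t) != nrow(q)) stop("t and q lengths differ")
  structure(list(t = as.numeric(t), q = unname(q)), class = "orientation_series")
}

#' Inertial sensor recording
#'
#' An [orientation_series()] plus synchronized gyroscope and accelerometer
#' streams in the sensor frame.
#'
#' @param t Timestamps (s).
#' @param q n x 4 unit quaternion matrix (global <- sensor).
#' @param gyro n x 3 angular velocity (rad/s), sensor frame; optional.
#' @param accel n x 3 specific force (m/s^2), sensor frame; optional.
#' @return Object of class `inertial_recording` (inherits
#'   `orientation_series`).
#' @export
inertial_recording <- function(t, q, gyro = NULL, accel = NULL) {
  base <- orientation_series(t, q)
  n <- length(base$t)
  chk3 <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n)
      stop(what, " must be an n x 3 matrix matching the timestamps")
    if (!all(is.finite(m))) stop("non-finite ", what, " samples")
    unname(m)
  }
  structure(c(base, list(gyro = chk3(gyro, "gyro"), accel = chk3(accel, "accel"))),
            class = c("inertial_recording", "orientation_series"))
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<%s> %d samples, %.2f s at ~%.1f Hz\n", class(x)[1],
              length(x$t), diff(range(x$t)),
              1 / stats::median(diff(x$t))))
  invisible(x)
}

#' Elbow joint angle time series
#'
#' @param t Timestamps (s).
#' @param flexion_deg,carrying_deg,pronation_deg Angle vectors (degrees).
#' @param gimbal Logical vector flagging samples near the carrying-angle
#'   singularity (default all `FALSE`).
#' @return Object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(t, flexion_deg, carrying_deg, pronation_deg,
                               gimbal = rep(FALSE, length(t))) {
  .check_time(t)
  n <- length(t)
  for (v in list(flexion_deg, carrying_deg, pronation_deg)) {
    if (length(v) != n || !all(is.finite(v))) stop("angle vectors must be finite and match t")
  }
  if (length(gimbal) != n) stop("gimbal flags must match t")
  structure(list(t = as.numeric(t),
                 flexion_deg = as.numeric(flexion_deg),
                 carrying_deg = as.numeric(carrying_deg),
                 pronation_deg = as.numeric(pronation_deg),
                 gimbal = as.logical(gimbal)),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf(
    "<joint_angle_series> %d samples; flexion [%.1f, %.1f], carrying [%.1f, %.1f], pronation [%.1f, %.1f] deg\n",
    length(x$t), min(x$flexion_deg), max(x$flexion_deg),
    min(x$carrying_deg), max(x$carrying_deg),
    min(x$pronation_deg), max(x$pronation_deg)))
  invisible(x)
}

#' @export
as.data.frame.joint_angle_series <- function(x, ...) {
  data.frame(t = x$t, flexion_deg = x$flexion_deg, carrying_deg = x$carrying_deg,
             pronation_deg = x$pronation_deg, gimbal_flag = x$gimbal)
}

.angle_column <- function(angles, axis) {
  switch(axis,
         flexion = angles$flexion_deg,
         carrying = angles$carrying_deg,
         pronation = angles$pronation_deg,
         stop("unknown axis: ", axis))
}
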