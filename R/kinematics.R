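# Runtime kinematics: apply a calibration quaternion to a sensor orientation
# stream and decompose the humerus->forearm relative rotation into the three
# elbow angles.

#' Apply a sensor-to-segment calibration to a runtime orientation stream
#'
#' Right-multiplies every global<-sensor sample by the calibration
#' quaternion q0 (segment -> sensor), yielding the global<-segment
#' orientation series.
#'
#' @param runtime [orientation_series()] of global<-sensor quaternions.
#' @param q0 Unit calibration quaternion.
#' @return [orientation_series()] of global<-segment quaternions.
#' @export
apply_calibration <- function(runtime, q0) {
  if (!inherits(runtime, "orientation_series")) stop("runtime must be an orientation_series")
  orientation_series(runtime$t, quat_multiply(runtime$q, quat_normalize(q0)))
}

#' Three-degree-of-freedom elbow joint angles
#'
#' Per sample, the relative rotation `inverse(q_upper) * q_lower`
#' (humerus <- forearm) is decomposed with the intrinsic Z-X'-Y'' sequence
#' into flexion/extension (Z), carrying angle (floating X) and
#' pronation/supination (Y). Flexion and pronation are phase-unwrapped;
#' samples near the carrying-angle singularity are flagged, not dropped.
#'
#' @param upper_arm,lower_arm Time-aligned [orientation_series()] of the two
#'   segment orientations (global <- segment).
#' @param unwrap Apply 360-degree phase unwrapping to flexion and pronation
#'   (default `TRUE`).
#' @return [joint_angle_series()] in degrees.
#' @export
elbow_angles <- function(upper_arm, lower_arm, unwrap = TRUE) {
  if (!inherits(upper_arm, "orientation_series") ||
      !inherits(lower_arm, "orientation_series"))
    stop("inputs must be orientation_series")
  if (length(upper_arm$t) != length(lower_arm$t) ||
      max(abs(upper_arm$t - lower_arm$t)) > 1e-9)
    stop("upper-arm and lower-arm series are not time-aligned")
  qrel <- quat_multiply(quat_inverse(upper_arm$q), lower_arm$q)
  ang <- zxy_angles_from_quat(qrel)
  fl <- ang$flexion_deg; pr <- ang$pronation_deg
  if (unwrap) {
    fl <- unwrap_deg(fl)
    pr <- unwrap_deg(pr)
  }
  joint_angle_series(upper_arm$t, fl, ang$carrying_deg, pr, ang$gimbal)
}
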