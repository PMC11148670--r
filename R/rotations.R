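# Orthonormal frame construction and the ZXY (intrinsic) Euler sequence used
# for the ISB elbow convention: first rotation about Z (flexion/extension),
# then about the floating X (carrying angle), then about Y
# (pronation/supination). Angles in degrees at every public boundary.

.AXIS_ROLES <- c("x", "y", "z")

.unit3 <- function(v, what = "vector") {
  if (length(v) != 3L || !all(is.finite(v))) stop(what, " must be a finite 3-vector")
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(what, " has zero norm")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# TRUE when (r1, r2, r3) is an even permutation of (x, y, z)
.even_perm <- function(roles) {
  paste(roles, collapse = "") %in% c("xyz", "yzx", "zxy")
}

#' Build a right-handed orthonormal frame from a primary and secondary axis
#'
#' The primary direction is kept exactly and assigned to the column named by
#' `roles[1]`; the secondary direction only fixes the plane (its component
#' along the primary is removed, Gram-Schmidt style) and lands in column
#' `roles[2]`. The third column completes a right-handed frame
#' (x cross y = z). This is the cross-product construction used to turn
#' measured anatomical directions (a hinge axis, the gravity line, a sensor
#' forward axis) into a full segment coordinate frame.
#'
#' @param primary Unit 3-vector, preserved exactly.
#' @param secondary 3-vector, not parallel to `primary` (angle > `min_angle_deg`).
#' @param roles Character vector of length 2: the axis labels ("x", "y", "z")
#'   receiving the primary and secondary directions.
#' @param min_angle_deg Minimum primary/secondary angle before the frame is
#'   declared degenerate (default 1 degree).
#' @return 3 x 3 rotation matrix; columns are the frame's x, y, z axes
#'   expressed in the coordinates of the input vectors.
#' @export
#' @examples
#' frame_from_axes(c(0, 0, 1), c(1, 0, 0), roles = c("z", "x"))  # identity
frame_from_axes <- function(primary, secondary, roles, min_angle_deg = 1) {
  p <- .unit3(primary, "primary axis")
  s <- .unit3(secondary, "secondary axis")
  roles <- match.arg(roles, .AXIS_ROLES, several.ok = TRUE)
  if (length(roles) != 2L || roles[1] == roles[2])
    stop("roles must name two distinct axes among x, y, z")
  ang <- atan2(sqrt(sum(.cross3(p, s)^2)), sum(p * s)) * 180 / pi
  if (min(ang, 180 - ang) < min_angle_deg) {
    stop(sprintf(
      "degenerate frame: primary and secondary axes are %.3f degrees apart (minimum %g)",
      ang, min_angle_deg))
  }
  r3 <- setdiff(.AXIS_ROLES, roles)
  sgn <- if (.even_perm(c(roles, r3))) 1 else -1
  a <- matrix(NA_real_, 3L, 3L, dimnames = list(NULL, .AXIS_ROLES))
  a[, roles[1]] <- p
  third <- sgn * .cross3(p, s)
  a[, r3] <- third / sqrt(sum(third^2))
  a[, roles[2]] <- sgn * .cross3(a[, r3], p)
  check_rotation_matrix(a)
  a
}

#' Compose a rotation from intrinsic Z-X'-Y'' Euler angles
#'
#' `R = Rz(flexion) Rx(carrying) Ry(pronation)`, the ISB elbow sequence.
#'
#' @param flexion_deg,carrying_deg,pronation_deg Angles in degrees (scalars).
#' @return 3 x 3 rotation matrix.
#' @export
euler_zxy_compose <- function(flexion_deg, carrying_deg, pronation_deg) {
  stopifnot(is.finite(flexion_deg), is.finite(carrying_deg), is.finite(pronation_deg))
  quat_to_matrix(quat_from_zxy(flexion_deg, carrying_deg, pronation_deg))
}

#' Quaternion of the intrinsic Z-X'-Y'' sequence (vectorized)
#'
#' @param flexion_deg,carrying_deg,pronation_deg Angle vectors in degrees,
#'   recycled to a common length.
#' @return Unit quaternion, or n x 4 matrix for vector input.
#' @export
quat_from_zxy <- function(flexion_deg, carrying_deg, pronation_deg) {
  n <- max(length(flexion_deg), length(carrying_deg), length(pronation_deg))
  a <- rep_len(flexion_deg, n) * pi / 360
  g <- rep_len(carrying_deg, n) * pi / 360
  b <- rep_len(pronation_deg, n) * pi / 360
  qz <- cbind(cos(a), 0, 0, sin(a))
  qx <- cbind(cos(g), sin(g), 0, 0)
  qy <- cbind(cos(b), 0, sin(b), 0)
  out <- quat_multiply(quat_multiply(qz, qx), qy)
  if (n == 1L) drop(out) else out
}

#' Decompose a rotation into intrinsic Z-X'-Y'' Euler angles
#'
#' Inverse of [euler_zxy_compose()]. Samples with the middle (carrying)
#' angle within `gimbal_margin_deg` of +/-90 degrees are flagged as
#' gimbal-proximal, not rejected.
#'
#' @param r 3 x 3 rotation matrix.
#' @param gimbal_margin_deg Flag margin around the +/-90 degree singularity.
#' @return List with `flexion_deg`, `carrying_deg`, `pronation_deg`
#'   (degrees; flexion and pronation in (-180, 180], carrying in
#'   `[-90, 90]`) and logical `gimbal`.
#' @export
euler_zxy_decompose <- function(r, gimbal_margin_deg = 0.5) {
  check_rotation_matrix(r)
  out <- zxy_angles_from_quat(matrix(quat_from_matrix(r), nrow = 1L),
                              gimbal_margin_deg = gimbal_margin_deg)
  lapply(out, drop)
}

#' ZXY Euler angles from quaternions (vectorized workhorse)
#'
#' @param q n x 4 matrix (or length-4 vector) of unit quaternions.
#' @param gimbal_margin_deg Flag margin around the carrying-angle singularity.
#' @return List of numeric vectors `flexion_deg`, `carrying_deg`,
#'   `pronation_deg` and logical vector `gimbal`.
#' @export
zxy_angles_from_quat <- function(q, gimbal_margin_deg = 0.5) {
  qm <- .qm(q)
  qm <- qm / .qnorm(qm)
  w <- qm[, 1]; x <- qm[, 2]; y <- qm[, 3]; z <- qm[, 4]
  r12 <- 2 * (x * y - w * z)
  r22 <- 1 - 2 * (x^2 + z^2)
  r32 <- 2 * (y * z + w * x)
  r31 <- 2 * (x * z - w * y)
  r33 <- 1 - 2 * (x^2 + y^2)
  carrying <- asin(pmin(pmax(r32, -1), 1)) * 180 / pi
  flexion <- atan2(-r12, r22) * 180 / pi
  pronation <- atan2(-r31, r33) * 180 / pi
  list(
    flexion_deg = flexion,
    carrying_deg = carrying,
    pronation_deg = pronation,
    gimbal = abs(abs(carrying) - 90) < gimbal_margin_deg
  )
}

#' Unwrap an angle series (degrees)
#'
#' Removes 360-degree jumps so that successive samples differ by less than
#' 180 degrees.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Unwrapped angle vector.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  corr <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  x + c(0, corr)
}
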