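# Quaternion algebra. Convention throughout the package: Hamilton product,
# scalar-first storage (w, x, y, z), passive rotations global <- local.
# Single quaternions are numeric vectors of length 4; time series are n x 4
# matrices. All operations accept either and broadcast a single row.

.QUAT_TOL <- 1e-9

# coerce to an n x 4 matrix, checking finiteness
.qm <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternions must have 4 components (w, x, y, z)")
  } else {
    if (length(q) != 4L) stop("quaternions must have 4 components (w, x, y, z)")
    q <- matrix(q, nrow = 1L)
  }
  if (!all(is.finite(q))) stop("non-finite quaternion components")
  q
}

.qnorm <- function(qm) sqrt(rowSums(qm^2))

#' Construct a unit quaternion
#'
#' Scalar-first Hamilton quaternion representing a passive rotation
#' (global <- local). The result is normalized; inputs whose norm deviates
#' from 1 by more than `tol_norm` are rejected.
#'
#' @param w,x,y,z Real components, scalar part first.
#' @param tol_norm Maximum tolerated deviation of the input norm from 1
#'   before normalization (default 1e-6; pass `Inf` to normalize any
#'   non-zero quaternion).
#' @return Numeric vector of length 4, class-free, unit norm.
#' @export
#' @examples
#' quat(1, 0, 0, 0)                        # identity
#' quat_from_axis_angle(c(0, 0, 1), 90)    # quarter turn about z
quat <- function(w, x, y, z, tol_norm = 1e-6) {
  q <- c(w, x, y, z)
  if (!all(is.finite(q))) stop("non-finite quaternion components")
  n <- sqrt(sum(q^2))
  if (n < .QUAT_TOL) stop("zero quaternion is not a rotation")
  if (abs(n - 1) > tol_norm) {
    stop(sprintf("quaternion norm %.6f deviates from 1 beyond tolerance", n))
  }
  q / n
}

#' Identity quaternion
#' @return The quaternion (1, 0, 0, 0).
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Normalize quaternions to unit norm
#'
#' @param q Quaternion (length-4 vector) or n x 4 matrix of quaternions.
#' @return Same shape as the input, each row scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  qm <- .qm(q)
  n <- .qnorm(qm)
  if (any(n < .QUAT_TOL)) stop("cannot normalize a zero quaternion")
  out <- qm / n
  if (!is.matrix(q)) out <- drop(out)
  out
}

#' Hamilton product of quaternions
#'
#' Composition order matches the matrix product of the corresponding
#' rotation matrices: `quat_to_matrix(quat_multiply(a, b))` equals
#' `quat_to_matrix(a) %*% quat_to_matrix(b)`. Row-wise over matrices, with
#' single rows recycled.
#'
#' @param a,b Quaternions (length-4 vectors or n x 4 matrices).
#' @return Renormalized product, matrix if either input was a matrix.
#' @export
quat_multiply <- function(a, b) {
  am <- .qm(a); bm <- .qm(b)
  na <- nrow(am); nb <- nrow(bm)
  if (na != nb) {
    if (na == 1L) am <- am[rep(1L, nb), , drop = FALSE]
    else if (nb == 1L) bm <- bm[rep(1L, na), , drop = FALSE]
    else stop("incompatible numbers of quaternions: ", na, " vs ", nb)
  }
  w <- am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4]
  x <- am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3]
  y <- am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2]
  z <- am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  out <- out / .qnorm(out)
  if (!is.matrix(a) && !is.matrix(b)) out <- drop(out)
  out
}

#' Inverse (conjugate) of unit quaternions
#'
#' @param q Quaternion or n x 4 matrix of unit quaternions.
#' @return Quaternion(s) such that `quat_multiply(q, quat_inverse(q))` is the
#'   identity rotation.
#' @export
quat_inverse <- function(q) {
  qm <- .qm(q)
  n <- .qnorm(qm)
  if (any(n < .QUAT_TOL)) stop("zero quaternion has no inverse")
  out <- cbind(qm[, 1], -qm[, 2], -qm[, 3], -qm[, 4], deparse.level = 0) / n
  if (!is.matrix(q)) out <- drop(out)
  out
}

#' Rotate 3-vectors by quaternions
#'
#' Applies the rotation represented by `q` (local coordinates into global
#' coordinates for a global<-local quaternion). Vectorized row-wise.
#'
#' @param q Quaternion or n x 4 matrix.
#' @param v 3-vector or n x 3 matrix.
#' @return Rotated vector(s), same shape rules as [quat_multiply()].
#' @export
quat_rotate <- function(q, v) {
  qm <- .qm(q)
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(vm) != 3L) stop("vectors must have 3 components")
  if (!all(is.finite(vm))) stop("non-finite vector components")
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1L && n > 1L) qm <- qm[rep(1L, n), , drop = FALSE]
  if (nrow(vm) == 1L && n > 1L) vm <- vm[rep(1L, n), , drop = FALSE]
  if (nrow(qm) != nrow(vm)) stop("incompatible numbers of quaternions and vectors")
  w <- qm[, 1]; u <- qm[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  cx <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  t1 <- cx(u, vm)
  out <- vm + 2 * w * t1 + 2 * cx(u, t1)
  if (!is.matrix(q) && !is.matrix(v)) out <- drop(out)
  out
}

#' Quaternion from axis and angle
#'
#' @param axis 3-vector, normalized internally.
#' @param angle_deg Rotation angle in degrees.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  if (length(axis) != 3L || !all(is.finite(axis))) stop("axis must be a finite 3-vector")
  n <- sqrt(sum(axis^2))
  if (n < .QUAT_TOL) stop("zero axis")
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

#' Rotation angle of (or between) quaternions, in degrees
#'
#' With one argument, the magnitude of the rotation `q` represents; with
#' two, the geodesic angle between the rotations `a` and `b`. Insensitive to
#' the q / -q sign ambiguity.
#'
#' @param a,b Quaternions or n x 4 matrices (`b` defaults to identity).
#' @return Angle(s) in `[0, 180]` degrees.
#' @export
quat_angle_deg <- function(a, b = quat_identity()) {
  am <- .qm(a); bm <- .qm(b)
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1L && n > 1L) am <- am[rep(1L, n), , drop = FALSE]
  if (nrow(bm) == 1L && n > 1L) bm <- bm[rep(1L, n), , drop = FALSE]
  am <- am / .qnorm(am); bm <- bm / .qnorm(bm)
  # chordal form: asin is well-conditioned near zero, unlike acos of the dot
  d <- pmin(sqrt(rowSums((am - bm)^2)), sqrt(rowSums((am + bm)^2)))
  out <- 4 * asin(pmin(d / 2, 1)) * 180 / pi
  if (!is.matrix(a) && !is.matrix(b)) out <- drop(out)
  out
}

#' Chordal mean of a quaternion series
#'
#' Sign-aligns all rows to the first sample, averages componentwise and
#' renormalizes. Adequate for tight clusters of orientations such as
#' calibration windows; not a general rotation average.
#'
#' @param q n x 4 matrix of unit quaternions.
#' @return Unit quaternion (length 4).
#' @export
quat_mean <- function(q) {
  qm <- .qm(q)
  s <- sign(qm %*% qm[1, ])
  s[s == 0] <- 1
  m <- colSums(qm * as.vector(s))
  n <- sqrt(sum(m^2))
  if (n < .QUAT_TOL) stop("quaternion mean is degenerate (antipodal samples)")
  m / n
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Unit quaternion (length 4).
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  q <- drop(.qm(q))
  if (length(q) != 4L) stop("quat_to_matrix expects a single quaternion")
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method; the returned quaternion has non-negative scalar part.
#'
#' @param r 3 x 3 rotation matrix (orthonormal, det +1).
#' @return Unit quaternion (length 4).
#' @export
quat_from_matrix <- function(r) {
  check_rotation_matrix(r)
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] >= r[2, 2] && r[1, 1] >= r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] >= r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Validate a rotation matrix
#'
#' @param r Candidate 3 x 3 matrix.
#' @param tol Orthonormality / determinant tolerance.
#' @return Invisibly `r`; errors if not a proper rotation.
#' @export
check_rotation_matrix <- function(r, tol = 1e-6) {
  if (!is.matrix(r) || any(dim(r) != 3L) || !all(is.finite(r)))
    stop("expected a finite 3 x 3 matrix")
  if (max(abs(crossprod(r) - diag(3))) > tol)
    stop("matrix columns are not orthonormal")
  if (abs(det(r) - 1) > tol)
    stop("matrix determinant is not +1 (improper rotation)")
  invisible(r)
}
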