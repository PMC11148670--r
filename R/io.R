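# Plain-text I/O. Orientation / inertial CSV schema:
#   t_s, qw, qx, qy, qz [, gx, gy, gz] [, ax, ay, az]
# Trials live in a directory with a manifest.json and one CSV per stream;
# this layout is the package's canonical fixture format.

.Q_COLS <- c("qw", "qx", "qy", "qz")
.G_COLS <- c("gx", "gy", "gz")
.A_COLS <- c("ax", "ay", "az")

#' Read an orientation / inertial CSV file
#'
#' Expects columns `t_s, qw, qx, qy, qz` and optionally `gx, gy, gz`
#' (gyroscope, rad/s) and `ax, ay, az` (accelerometer, m/s^2). Rows with
#' missing values are reported by number; quaternion norms deviating more
#' than 1% from unity are rejected, the rest renormalized.
#'
#' @param path CSV file path.
#' @return [inertial_recording()] when inertial columns are present,
#'   otherwise [orientation_series()].
#' @export
load_orientation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("t_s", .Q_COLS)
  if (!all(need %in% names(d)))
    stop("schema mismatch in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  has_g <- all(.G_COLS %in% names(d))
  has_a <- all(.A_COLS %in% names(d))
  used <- c(need, if (has_g) .G_COLS, if (has_a) .A_COLS)
  bad <- which(!stats::complete.cases(d[used]))
  if (length(bad))
    stop("missing/NaN values in ", path, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  q <- as.matrix(d[.Q_COLS])
  if (has_g || has_a) {
    inertial_recording(d$t_s, q,
                       gyro = if (has_g) as.matrix(d[.G_COLS]),
                       accel = if (has_a) as.matrix(d[.A_COLS]))
  } else {
    orientation_series(d$t_s, q)
  }
}

#' Write an orientation series / inertial recording to CSV
#'
#' @param x [orientation_series()] or [inertial_recording()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_orientation_csv <- function(x, path) {
  stopifnot(inherits(x, "orientation_series"))
  d <- data.frame(t_s = x$t)
  d[.Q_COLS] <- x$q
  if (!is.null(x$gyro)) d[.G_COLS] <- x$gyro
  if (!is.null(x$accel)) d[.A_COLS] <- x$accel
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a joint angle series as tidy CSV
#'
#' Columns `t, flexion_deg, carrying_deg, pronation_deg, gimbal_flag`,
#' angles with six decimal places.
#'
#' @param x [joint_angle_series()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_joint_angles_csv <- function(x, path) {
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits = 6)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a metric table as tidy CSV
#'
#' @param metrics Metric `data.frame` from [compute_metrics()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_metrics_csv <- function(metrics, path) {
  d <- metrics
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits = 6)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration result to JSON
#'
#' @param x [calibration_result()].
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_calibration_json <- function(x, path) {
  stopifnot(inherits(x, "calibration_result"))
  jsonlite::write_json(list(method = x$method,
                            q0_upper_arm = x$q0_upper_arm,
                            q0_lower_arm = x$q0_lower_arm,
                            diagnostics = x$diagnostics),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration result from JSON
#'
#' @param path JSON path written by [write_calibration_json()].
#' @return [calibration_result()].
#' @export
read_calibration_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_result(d$method, d$q0_upper_arm, d$q0_lower_arm,
                     as.list(d$diagnostics))
}

#' Write a synthetic trial to a directory
#'
#' Creates `manifest.json` (task, seed, profile scalars) plus one CSV per
#' stream: the ground-truth angles, the three ground-truth segment
#' orientations and the three corrupted IMU streams.
#'
#' @param trial `synthetic_trial` from [generate_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- trial$profile
  manifest <- list(
    format = "elbowcal-trial-v1", task = trial$task, seed = p$seed,
    profile = p[c("carrying_angle_baseline_deg", "carrying_angle_span_deg",
                  "carrying_shape", "npose_posture_error_deg", "gyro_noise_sd",
                  "accel_noise_sd", "heading_drift_dps")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(trial$truth_angles),
                   file.path(dir, "truth_angles.csv"), row.names = FALSE)
  for (s in names(trial$truth_orientations))
    write_orientation_csv(trial$truth_orientations[[s]],
                          file.path(dir, paste0("truth_", s, ".csv")))
  for (s in names(trial$imu_streams))
    write_orientation_csv(trial$imu_streams[[s]],
                          file.path(dir, paste0("imu_", s, ".csv")))
  invisible(dir)
}

#' Read a trial directory written by [write_trial()]
#'
#' @param dir Trial directory containing `manifest.json`.
#' @return List mirroring a `synthetic_trial` (profile reduced to the
#'   manifest scalars).
#' @export
read_trial <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a trial directory (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "elbowcal-trial-v1"))
    stop("unsupported trial format in ", dir, ": ",
         if (is.null(manifest$format)) "<missing>" else manifest$format)
  ang <- utils::read.csv(file.path(dir, "truth_angles.csv"))
  truth <- list(); imu <- list()
  for (s in .SENSORS) {
    tf <- file.path(dir, paste0("truth_", s, ".csv"))
    mf2 <- file.path(dir, paste0("imu_", s, ".csv"))
    if (file.exists(tf)) truth[[s]] <- load_orientation_csv(tf)
    if (file.exists(mf2)) imu[[s]] <- load_orientation_csv(mf2)
  }
  structure(list(task = manifest$task,
                 truth_angles = joint_angle_series(ang$t, ang$flexion_deg,
                                                   ang$carrying_deg,
                                                   ang$pronation_deg,
                                                   as.logical(ang$gimbal_flag)),
                 truth_orientations = truth, imu_streams = imu,
                 profile = manifest$profile), class = "trial_on_disk")
}

#' Load a local copy of the study data deposit
#'
#' Adapter mapping an on-disk dataset into the package's trial
#' representation. Directories following the package's native layout (trial
#' subdirectories each holding an `elbowcal-trial-v1` manifest) are read
#' with [read_trial()]; any other layout raises an explicit
#' unsupported-format error rather than guessing.
#'
#' @param path Root directory of the dataset.
#' @return Named list of trials (one element per trial subdirectory).
#' @export
load_zenodo_adapter <- function(path) {
  if (!dir.exists(path)) stop("dataset directory does not exist: ", path)
  subs <- list.dirs(path, recursive = FALSE)
  trials <- subs[file.exists(file.path(subs, "manifest.json"))]
  if (!length(trials))
    stop("unsupported dataset layout under ", path,
         ": no trial subdirectories with manifest.json were found; ",
         "only the native elbowcal-trial-v1 layout is supported")
  out <- lapply(trials, read_trial)
  names(out) <- basename(trials)
  out
}
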