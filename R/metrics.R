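# Per-repetition agreement metrics between a reference (optical-grade) and a
# test (IMU) joint angle series: range-of-motion error, RMSE of the
# within-repetition demeaned series, and offset of the means.

#' Segment a trial into movement repetitions
#'
#' Cuts the series at consecutive local minima of the smoothed dominant-axis
#' signal (0.25 s moving average by default), the natural boundaries of
#' cyclic movement protocols that start near the movement minimum. Windows
#' shorter than half the typical cycle are discarded; a warning is raised if
#' the number of windows found differs from `expected`.
#'
#' @param angles [joint_angle_series()].
#' @param dominant_axis `"flexion"`, `"pronation"` or `"carrying"`: the axis
#'   carrying the movement cycles.
#' @param expected Number of repetitions the protocol prescribes.
#' @param smooth_s Moving-average window (seconds) applied before minima
#'   detection (default 0.25).
#' @param min_range_deg Minimum peak-to-peak range (degrees) on the dominant
#'   axis; flatter signals raise an error (default 10).
#' @return List of `repetition_window` objects: `start` and `end` sample
#'   indices (half-open `[start, end)`) and ordinal `label`.
#' @export
segment_repetitions <- function(angles, dominant_axis = "flexion", expected = 5,
                                smooth_s = 0.25, min_range_deg = 10) {
  x <- .angle_column(angles, dominant_axis)
  n <- length(x)
  if (n < 2L * expected) stop("series too short for ", expected, " repetitions")
  rng <- diff(range(x))
  if (rng < min_range_deg)
    stop(sprintf("flat signal: %s range %.1f deg is below %g deg",
                 dominant_axis, rng, min_range_deg))
  dt <- stats::median(diff(angles$t))
  k <- max(1L, round(smooth_s / dt))
  if (k > 1L) {
    xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    xs[is.na(xs)] <- x[is.na(xs)]
  } else xs <- x
  # interior local minima in the lower part of the signal's range
  lo <- min(xs) + 0.45 * diff(range(xs))
  idx <- which(xs[2:(n - 1)] <= xs[1:(n - 2)] & xs[2:(n - 1)] <= xs[3:n] &
                 xs[2:(n - 1)] < lo) + 1L
  # collapse runs/clusters closer than half a nominal cycle, keeping the deepest
  if (length(idx)) {
    min_sep <- max(2L, floor(n / (2L * expected)))
    keep <- integer(0)
    grp <- split(idx, cumsum(c(1L, diff(idx) > min_sep)))
    for (g in grp) keep <- c(keep, g[which.min(xs[g])])
    idx <- keep
  }
  cuts <- unique(c(1L, idx, n + 1L))
  len <- diff(cuts)
  ok <- len >= 0.5 * stats::median(len)
  starts <- cuts[-length(cuts)][ok]
  ends <- cuts[-1L][ok]
  if (length(starts) != expected)
    warning(sprintf("found %d repetition window(s) where %d were expected",
                    length(starts), expected))
  mapply(function(s, e, i) {
    structure(list(start = s, end = e, label = i), class = "repetition_window")
  }, starts, ends, seq_along(starts), SIMPLIFY = FALSE)
}

#' Range-of-motion error (degrees)
#'
#' Difference between the reference and test peak-to-peak ranges:
#' `(max - min)(reference) - (max - min)(test)`. Invariant to constant
#' shifts of either input.
#'
#' @param opto Reference angle samples (degrees).
#' @param imu Test angle samples (degrees).
#' @return Scalar ROM error in degrees.
#' @export
rom_error <- function(opto, imu) {
  if (!length(opto) || !length(imu)) stop("empty input")
  (max(opto) - min(opto)) - (max(imu) - min(imu))
}

#' Root-mean-square error of the demeaned series (degrees)
#'
#' Each series is first demeaned by its own within-repetition mean, so a
#' constant offset between the systems does not contribute; what remains is
#' the waveform (shape and amplitude) disagreement.
#'
#' @inheritParams rom_error
#' @return Scalar RMSE in degrees (non-negative).
#' @export
rmse <- function(opto, imu) {
  if (length(opto) != length(imu)) stop("length mismatch between reference and test series")
  if (length(opto) < 2L) stop("need at least 2 samples")
  d <- (opto - mean(opto)) - (imu - mean(imu))
  sqrt(mean(d^2))
}

#' Offset between reference and test means (degrees)
#'
#' `mean(reference) - mean(test)` within the repetition.
#'
#' @inheritParams rom_error
#' @return Scalar offset in degrees.
#' @export
offset <- function(opto, imu) {
  if (!length(opto) || !length(imu)) stop("empty input")
  mean(opto) - mean(imu)
}

#' Per-repetition metric table for one trial
#'
#' One row per repetition window and joint axis, holding the three
#' agreement metrics between the reference and test angle series.
#'
#' @param reference,test Time-aligned [joint_angle_series()] (reference in
#'   the role of the optical system).
#' @param windows List of repetition windows from [segment_repetitions()].
#' @param meta Named list of labels attached to every row: `subject`,
#'   `calibration`, `task` (missing entries become `NA`).
#' @return `data.frame` with columns subject, calibration, task, axis,
#'   repetition, rom_error_deg, rmse_deg, offset_deg.
#' @export
compute_metrics <- function(reference, test, windows,
                            meta = list(subject = NA, calibration = NA, task = NA)) {
  if (length(reference$t) != length(test$t) ||
      max(abs(reference$t - test$t)) > 1e-9)
    stop("reference and test series are not time-aligned")
  axes <- c("flexion", "carrying", "pronation")
  lab <- function(k) if (is.null(meta[[k]])) NA else meta[[k]]
  rows <- list()
  for (w in windows) {
    if (w$start < 1L || w$end > length(reference$t) + 1L || w$start >= w$end)
      stop("repetition window out of range")
    sel <- seq.int(w$start, w$end - 1L)
    for (ax in axes) {
      r <- .angle_column(reference, ax)[sel]
      s <- .angle_column(test, ax)[sel]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = lab("subject"), calibration = lab("calibration"),
        task = lab("task"), axis = ax, repetition = w$label,
        rom_error_deg = rom_error(r, s), rmse_deg = rmse(r, s),
        offset_deg = offset(r, s), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
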