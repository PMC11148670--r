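# End-to-end study runner: simulate -> calibrate -> angles -> per-repetition
# metrics -> repeated-measures summaries. The ground-truth angle series plays
# the role of the optical reference; the corrupted IMU streams, calibrated by
# each method, play the role of the wearable system.

.FIVE_TASKS <- c("flexion", "pronation", "drinking", "box_off_shelf", "circles")

.dominant_axis <- function(task) if (task == "pronation") "pronation" else "flexion"

#' Configuration for a synthetic study run
#'
#' @param calibrations Subset of `c("NP", "FC", "MA")` to evaluate.
#' @param tasks Subset of the five movement tasks.
#' @param n_subjects Number of simulated subjects (default 13).
#' @param seed Master seed; every random draw in the run derives from it.
#' @param ranges Subject profile ranges ([study_profile_ranges()]).
#' @param rate_hz Sampling rate (default 60).
#' @param reps Movement repetitions per trial (default 5).
#' @param task_duration_s Task trial length (default 15 s).
#' @param output_dir Optional directory; when set, [run_study()] writes the
#'   metric and effects tables there as CSV.
#' @return Object of class `study_config`.
#' @export
study_config <- function(calibrations = c("NP", "FC", "MA"),
                         tasks = .FIVE_TASKS,
                         n_subjects = 13, seed = 1,
                         ranges = study_profile_ranges(),
                         rate_hz = 60, reps = 5, task_duration_s = 15,
                         output_dir = NULL) {
  calibrations <- match.arg(calibrations, c("NP", "FC", "MA"), several.ok = TRUE)
  tasks <- match.arg(tasks, .FIVE_TASKS, several.ok = TRUE)
  if (!length(calibrations) || !length(tasks))
    stop("calibration and task sets must be non-empty")
  if (is.null(seed) || !is.finite(seed)) stop("a seed is required")
  structure(list(calibrations = calibrations, tasks = tasks,
                 n_subjects = n_subjects, seed = as.integer(seed),
                 ranges = ranges, rate_hz = rate_hz, reps = reps,
                 task_duration_s = task_duration_s, output_dir = output_dir),
            class = "study_config")
}

.calibrate_subject <- function(trials, methods) {
  out <- list()
  if ("NP" %in% methods) {
    st <- trials$npose_static$imu_streams
    out$NP <- calibrate_npose(list(thorax = st$thorax, upper_arm = st$upper_arm,
                                   lower_arm = st$lower_arm))
  }
  if ("FC" %in% methods) {
    out$FC <- calibrate_functional(fe_ua = trials$fe_calibration$imu_streams$upper_arm,
                                   fe_la = trials$fe_calibration$imu_streams$lower_arm,
                                   ps_la = trials$ps_calibration$imu_streams$lower_arm)
  }
  if ("MA" %in% methods) out$MA <- calibrate_manual()
  out
}

#' Run the full synthetic study pipeline
#'
#' For every subject, calibrates each requested method from that subject's
#' calibration trials, applies it to the IMU streams of each requested task,
#' computes the elbow angles from both the ground truth (reference role) and
#' the calibrated IMU data, segments repetitions on the reference's dominant
#' axis, and emits the per-repetition metric table. The three dependent
#' variables are then summarised with [rm_anova_three_way()] (when at least
#' two calibrations and two tasks are present). Fully deterministic given
#' the config seed.
#'
#' @param config [study_config()].
#' @return Object of class `study_result`: list with `metrics` (one row per
#'   subject x calibration x task x axis x repetition), `anova` (per
#'   dependent variable, or `NULL` when the design is too small), `summary`
#'   (per-calibration means and IQRs), and `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  study <- generate_study(config$n_subjects, config$seed, config$ranges,
                          rate_hz = config$rate_hz, reps = config$reps,
                          task_duration_s = config$task_duration_s)
  metrics <- list()
  for (subj in study$subjects) {
    cals <- tryCatch(.calibrate_subject(subj$trials, config$calibrations),
                     error = function(e) stop("calibration failed for ", subj$id,
                                              ": ", conditionMessage(e)))
    for (task in config$tasks) {
      trial <- subj$trials[[task]]
      ref <- trial$truth_angles
      windows <- withCallingHandlers(
        segment_repetitions(ref, .dominant_axis(task), expected = config$reps),
        warning = function(w) {
          warning(subj$id, "/", task, ": ", conditionMessage(w), call. = FALSE)
          invokeRestart("muffleWarning")
        })
      for (m in names(cals)) {
        ua <- apply_calibration(trial$imu_streams$upper_arm, cals[[m]]$q0_upper_arm)
        la <- apply_calibration(trial$imu_streams$lower_arm, cals[[m]]$q0_lower_arm)
        test <- elbow_angles(ua, la)
        metrics[[length(metrics) + 1L]] <- compute_metrics(
          ref, test, windows,
          meta = list(subject = subj$id, calibration = m, task = task))
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  anova <- NULL
  if (length(config$calibrations) >= 2L && config$n_subjects >= 3L &&
      length(config$tasks) >= 2L) {
    anova <- lapply(c(rom_error = "rom_error", rmse = "rmse", offset = "offset"),
                    function(dv) rm_anova_three_way(metrics, dv = dv))
  }
  summary <- summarize_metrics(metrics)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(metrics, file.path(config$output_dir, "metrics.csv"))
    if (!is.null(anova)) {
      for (dv in names(anova)) {
        utils::write.csv(anova[[dv]],
                         file.path(config$output_dir, paste0("anova_", dv, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  structure(list(metrics = metrics, anova = anova, summary = summary,
                 config = config), class = "study_result")
}

#' Aggregate the metric table to per-calibration summaries
#'
#' Repetition-averages each subject x calibration x task x axis cell, then
#' reports the mean, the mean absolute value and the interquartile range of
#' each metric by calibration (and by calibration x axis).
#'
#' @param metrics Metric `data.frame` from [run_study()] / [compute_metrics()].
#' @return List with `by_calibration` and `by_calibration_axis` data frames.
#' @export
summarize_metrics <- function(metrics) {
  cols <- c("rom_error_deg", "rmse_deg", "offset_deg")
  cell <- stats::aggregate(metrics[cols],
                           metrics[c("subject", "calibration", "task", "axis")],
                           FUN = mean)
  agg <- function(by) {
    m <- stats::aggregate(cell[cols], cell[by], FUN = mean)
    iqr <- stats::aggregate(cell[cols], cell[by], FUN = stats::IQR)
    names(iqr)[match(cols, names(iqr))] <- paste0(cols, "_iqr")
    merge(m, iqr, by = by, sort = TRUE)
  }
  list(by_calibration = agg("calibration"),
       by_calibration_axis = agg(c("calibration", "axis")))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d metric rows; %d subjects, calibrations %s\n",
              nrow(x$metrics), x$config$n_subjects,
              paste(x$config$calibrations, collapse = "/")))
  print(x$summary$by_calibration, digits = 3)
  invisible(x)
}
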