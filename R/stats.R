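# Repeated-measures summaries of the metric table: a three-way
# fully-within-subject ANOVA (calibration x axis x task) per dependent
# variable, with Greenhouse-Geisser correction where sphericity is violated,
# and generalized eta squared effect sizes.

#' Generalized eta squared
#'
#' Effect size for (repeated-measures) designs following Bakeman's
#' formulation: the effect sum of squares over the effect plus all variance
#' components attributable to subjects, i.e. every error stratum of the
#' design including the between-subject one.
#'
#' @param ss_effect Sum of squares of the effect (non-negative scalar).
#' @param ss_subject_and_error_terms Numeric vector (or list) of the
#'   subject-related and error sums of squares entering the denominator.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' generalized_eta_squared(10, c(50, 40))  # 0.1
generalized_eta_squared <- function(ss_effect, ss_subject_and_error_terms) {
  ss_err <- unlist(ss_subject_and_error_terms)
  if (ss_effect < 0 || any(ss_err < 0)) stop("sums of squares must be non-negative")
  denom <- ss_effect + sum(ss_err)
  if (denom <= 0) stop("all-zero sums of squares: effect size undefined")
  ss_effect / denom
}

.rm_check_complete <- function(d) {
  tab <- table(d$subject, d$calibration, d$axis, d$task)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    dn <- dimnames(tab)
    ex <- apply(utils::head(miss, 5L), 1L, function(i)
      paste(dn[[1]][i[1]], dn[[2]][i[2]], dn[[3]][i[3]], dn[[4]][i[4]], sep = "/"))
    stop("incomplete crossed design; missing cells (subject/calibration/axis/task): ",
         paste(ex, collapse = ", "),
         if (nrow(miss) > 5L) sprintf(" and %d more", nrow(miss) - 5L) else "")
  }
  invisible(TRUE)
}

#' Three-way repeated-measures ANOVA over the metric table
#'
#' Repetition-averages the metric records into one value per subject x
#' calibration x axis x task cell, then fits the fully-within-subject
#' calibration x axis x task ANOVA for the chosen dependent variable. The
#' univariate F tests, Mauchly sphericity tests and Greenhouse-Geisser
#' epsilons are delegated to [car::Anova()]; degrees of freedom and p-values
#' are Greenhouse-Geisser-corrected for effects whose Mauchly test is
#' significant at `sphericity_alpha`. Generalized eta squared is computed
#' with [generalized_eta_squared()], pooling every error stratum of the
#' design (including the between-subject one) into the denominator.
#'
#' @param records Metric `data.frame` from [compute_metrics()] /
#'   [run_study()] with columns subject, calibration, axis, task,
#'   repetition and the metric columns.
#' @param dv Dependent variable: `"rom_error"`, `"rmse"` or `"offset"`.
#' @param effects Effect names to report, in `car` notation over the factors
#'   `calibration`, `axis`, `task`.
#' @param sphericity_alpha Mauchly significance level triggering the
#'   Greenhouse-Geisser correction (default 0.05).
#' @return `data.frame` with one row per effect: `effect`, `df_num`,
#'   `df_den` (corrected where applicable), `F`, `p`, `ges`, the sums of
#'   squares behind the effect size (`ss_effect`, `ss_error_total`),
#'   `mauchly_p` and `gg_applied`.
#' @export
rm_anova_three_way <- function(records,
                               dv = c("rom_error", "rmse", "offset"),
                               effects = c("calibration", "calibration:axis",
                                           "calibration:task"),
                               sphericity_alpha = 0.05) {
  dv <- match.arg(dv)
  col <- paste0(dv, "_deg")
  if (!col %in% names(records)) stop("records lack a ", col, " column")
  d <- records
  for (k in c("subject", "calibration", "axis", "task")) {
    if (!k %in% names(d)) stop("records lack a ", k, " column")
    d[[k]] <- factor(d[[k]])
  }
  d$y <- d[[col]]
  # average over repetitions -> one observation per within-subject cell
  cell <- stats::aggregate(y ~ subject + calibration + axis + task, data = d, FUN = mean)
  .rm_check_complete(cell)
  subjects <- levels(cell$subject)
  if (length(subjects) < 3L) stop("need at least 3 subjects")
  idata <- expand.grid(task = levels(cell$task), axis = levels(cell$axis),
                       calibration = levels(cell$calibration),
                       KEEP.OUT.ATTRS = FALSE)
  key <- function(df) paste(df$calibration, df$axis, df$task, sep = "\r")
  cell_key <- key(cell)
  Y <- matrix(NA_real_, length(subjects), nrow(idata))
  for (i in seq_along(subjects)) {
    rows <- cell$subject == subjects[i]
    Y[i, ] <- cell$y[rows][match(key(idata), cell_key[rows])]
  }
  if (stats::var(as.vector(Y)) < 1e-16) {
    # degenerate (e.g. error-free closed loop): no variance to partition
    return(data.frame(effect = effects, df_num = NA_real_, df_den = NA_real_,
                      F = 0, p = 1, ges = 0, ss_effect = 0,
                      ss_error_total = 0, mauchly_p = NA_real_,
                      gg_applied = FALSE, stringsAsFactors = FALSE))
  }
  mod <- stats::lm(Y ~ 1)
  an <- car::Anova(mod, idata = idata, idesign = ~ calibration * axis * task,
                   type = "III")
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  ut <- s$univariate.tests
  ss_all_error <- sum(ut[, "Error SS"])
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  out <- lapply(effects, function(e) {
    if (!e %in% rownames(ut)) stop("unknown effect: ", e)
    ss <- ut[e, "Sum Sq"]
    dfn <- ut[e, "num Df"]; dfd <- ut[e, "den Df"]
    Fv <- ut[e, "F value"]; p <- ut[e, "Pr(>F)"]
    if (!is.finite(Fv) && ss < 1e-12) { Fv <- 0; p <- 1 }  # exact-null effect
    mau <- if (!is.null(sph) && e %in% rownames(sph)) sph[e, "p-value"] else NA_real_
    gg <- FALSE
    if (is.finite(mau) && mau < sphericity_alpha &&
        !is.null(adj) && e %in% rownames(adj) && is.finite(adj[e, "GG eps"])) {
      eps <- min(1, adj[e, "GG eps"])
      dfn <- dfn * eps; dfd <- dfd * eps
      p <- adj[e, "Pr(>F[GG])"]
      gg <- TRUE
    }
    ges <- if (ss == 0 && ss_all_error == 0) 0
           else generalized_eta_squared(ss, ss_all_error)
    data.frame(effect = e, df_num = dfn, df_den = dfd, F = Fv, p = p,
               ges = ges, ss_effect = ss, ss_error_total = ss_all_error,
               mauchly_p = mau, gg_applied = gg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
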