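#' Explained variance of measured PSEs under the integration model
#'
#' The proportion of variance in the measured PSEs explained by the model
#' predictions,
#' `R^2 = 1 - (1 / (var_pred + var_meas)) * mean((S - S_hat)^2)`,
#' where the two variances are population variances (denominator `N`) of
#' the predicted and measured PSE sets. `R^2 = 1` means the predictions
#' match the measurements exactly; `R^2 = 0` means the model does no
#' better than the mean of the data (the constant-prediction case gives
#' exactly 0); `R^2 < 0` means it does worse.
#'
#' @param measured numeric vector of measured (bias-corrected) PSEs, all
#'   observers and all conflict levels of a group.
#' @param predicted matching vector of model-predicted PSEs.
#' @param age_group optional label stored in the result.
#' @return Object of class `"variance_explained"`: `age_group`,
#'   `n_points`, `mean_sq_err`, `var_predicted`, `var_measured`,
#'   `r_squared`.
#' @examples
#' s <- c(-3, -1, 0, 2, 4)
#' r_squared(s, s)$r_squared          # 1
#' r_squared(s, rep(mean(s), 5))$r_squared  # 0
#' @export
r_squared <- function(measured, predicted, age_group = NA_character_) {
  stopifnot(is.numeric(measured), is.numeric(predicted),
            length(measured) == length(predicted))
  n <- length(measured)
  if (n < 2L) stop("need at least two PSE values", call. = FALSE)
  pvar <- function(v) mean((v - mean(v))^2)
  var_m <- pvar(measured)
  var_p <- pvar(predicted)
  if (var_m + var_p <= 0) {
    stop("measured and predicted PSEs are both constant", call. = FALSE)
  }
  mse <- mean((measured - predicted)^2)
  structure(list(age_group = age_group, n_points = n,
                 mean_sq_err = mse, var_predicted = var_p,
                 var_measured = var_m,
                 r_squared = 1 - mse / (var_p + var_m)),
            class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  cat(sprintf("<variance_explained> %s: R^2 = %.3f (N = %d)\n",
              x$age_group, x$r_squared, x$n_points))
  invisible(x)
}

#' One-tailed test of bimodal thresholds against the MLE prediction
#'
#' One-sample t-test on the per-observer differences
#' `measured bimodal sigma - predicted sigma_VA`, one-tailed with
#' alternative "measured > predicted" — the direction in which an observer
#' falls short of the optimal (lower) bimodal bound. Stars at 0.05 and
#' 0.01 as in the usual group plots.
#'
#' @param measured per-observer measured bimodal thresholds.
#' @param predicted matching MLE-predicted thresholds.
#' @param age_group optional label.
#' @return Object of class `"threshold_comparison"`: `age_group`,
#'   `t_stat`, `p_one_tailed`, `n`, `mean_diff`, `significant_05`,
#'   `significant_01`, `degenerate` (zero variance of differences).
#' @export
compare_bimodal_to_prediction <- function(measured, predicted,
                                          age_group = NA_character_) {
  stopifnot(is.numeric(measured), is.numeric(predicted),
            length(measured) == length(predicted))
  n <- length(measured)
  if (n < 2L) stop("need at least two observers", call. = FALSE)
  d <- measured - predicted
  if (stats::sd(d) == 0) {
    m <- mean(d)
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    degenerate <- TRUE
  } else {
    tt <- stats::t.test(d, mu = 0, alternative = "greater")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    degenerate <- FALSE
  }
  structure(list(age_group = age_group, t_stat = t_stat, p_one_tailed = p,
                 n = n, mean_diff = mean(d),
                 significant_05 = p < 0.05, significant_01 = p < 0.01,
                 degenerate = degenerate),
            class = "threshold_comparison")
}

#' @export
print.threshold_comparison <- function(x, ...) {
  stars <- if (x$significant_01) "**" else if (x$significant_05) "*" else ""
  cat(sprintf("<threshold_comparison> %s: t = %.3f, one-tailed p = %.4f (n = %d) %s\n",
              x$age_group, x$t_stat, x$p_one_tailed, x$n, stars))
  invisible(x)
}

#' Group-level summaries by age
#'
#' Produces the age-binned summary tables: mean +/- SEM of unimodal,
#' bimodal, and predicted thresholds and of the two weight estimates per
#' age group; the explained-variance statistic per group over all children
#' and all conflict levels; and the one-tailed bimodal-vs-prediction
#' threshold test per group.
#'
#' @param observers per-observer summary data frame (one row per
#'   observer), as produced by [run_pipeline()] / [analyze_observer()]:
#'   needs columns `age_group`, `sigma_V`, `sigma_A`, `sigma_bimodal`,
#'   `sigma_pred`, `w_A_thresholds`, `w_A_slope`.
#' @param pses per-observer-per-conflict PSE data frame with columns
#'   `age_group`, `pse_corrected`, `pse_predicted` (conflict 0 rows are
#'   kept: they anchor both vectors at 0).
#' @return List with `summary` (data frame, one row per age group),
#'   `r_squared` (list of `"variance_explained"`), `threshold_tests`
#'   (list of `"threshold_comparison"`).
#' @export
aggregate_by_age <- function(observers, pses) {
  stopifnot(is.data.frame(observers), "age_group" %in% names(observers))
  groups <- unique(observers$age_group)
  sem <- function(v) {
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  rows <- list(); r2 <- list(); tests <- list()
  for (g in groups) {
    og <- observers[observers$age_group == g, , drop = FALSE]
    if (nrow(og) == 0L) {
      warning(sprintf("age group '%s' is empty; omitted", g))
      next
    }
    rows[[g]] <- data.frame(
      age_group = g, n = nrow(og),
      sigma_V = mean(og$sigma_V), sigma_V_sem = sem(og$sigma_V),
      sigma_A = mean(og$sigma_A), sigma_A_sem = sem(og$sigma_A),
      sigma_bimodal = mean(og$sigma_bimodal),
      sigma_bimodal_sem = sem(og$sigma_bimodal),
      sigma_pred = mean(og$sigma_pred), sigma_pred_sem = sem(og$sigma_pred),
      w_A_thresholds = mean(og$w_A_thresholds),
      w_A_thresholds_sem = sem(og$w_A_thresholds),
      w_A_slope = mean(og$w_A_slope), w_A_slope_sem = sem(og$w_A_slope),
      sem_defined = nrow(og) >= 2L
    )
    pg <- pses[pses$age_group == g, , drop = FALSE]
    if (nrow(pg) >= 2L) {
      r2[[g]] <- tryCatch(
        r_squared(pg$pse_corrected, pg$pse_predicted, age_group = g),
        error = function(e) NULL)
    }
    if (nrow(og) >= 2L) {
      tests[[g]] <- compare_bimodal_to_prediction(
        og$sigma_bimodal, og$sigma_pred, age_group = g)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, r_squared = r2, threshold_tests = tests)
}
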