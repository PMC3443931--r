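#' Per-observer analysis of a fitted session
#'
#' Turns one observer's session fits into the quantities the group-level
#' analysis consumes: fitted unimodal thresholds, the pooled bimodal
#' threshold, the MLE prediction (predicted bimodal threshold and
#' threshold-derived weights), bias-corrected PSEs in the symmetric
#' conflict frame, the PSE-versus-conflict slope, and the slope-derived
#' auditory weight.
#'
#' @param session a `"bisection_session"`.
#' @param fits optional precomputed [fit_session()] result (computed here
#'   otherwise).
#' @param n_boot,seed forwarded to [fit_session()] when `fits` is missing.
#' @param weighted_regression use inverse-variance weights in
#'   [slope_from_pses()].
#' @return List of class `"observer_analysis"` with `observer` (one-row
#'   summary data frame), `pses` (per-conflict data frame with raw,
#'   corrected, and predicted PSEs), `fits`, `slope`, `prediction`.
#' @export
analyze_observer <- function(session, fits = NULL, n_boot = 100L,
                             seed = NULL, weighted_regression = FALSE) {
  stopifnot(inherits(session, "bisection_session"))
  if (is.null(fits)) fits <- fit_session(session, n_boot = n_boot, seed = seed)
  stopifnot(inherits(fits, "session_fits"))

  f_V <- fits$fits[["visual"]]
  f_A <- fits$fits[["auditory"]]
  bi_keys <- grep("^bimodal@", names(fits$fits), value = TRUE)
  bi_fits <- fits$fits[bi_keys]

  pred <- mle_prediction(f_V$threshold, f_A$threshold,
                         conflicts = vapply(bi_fits, `[[`, numeric(1L),
                                            "conflict"))
  corr <- conflict_pse(bi_fits, session$domain)
  sl <- slope_from_pses(corr, weighted = weighted_regression)
  w_slope <- weights_from_slope(sl)

  pses <- data.frame(
    observer_id = session$observer_id,
    age_group = session$age_group,
    domain = session$domain,
    conflict = corr$conflict,
    pse_raw = vapply(bi_fits, `[[`, numeric(1L), "pse"),
    pse_corrected = corr$pse_corrected,
    pse_se = corr$pse_se,
    pse_predicted = predict_pse(pred$weights, corr$conflict)
  )
  rownames(pses) <- NULL

  observer <- data.frame(
    observer_id = session$observer_id,
    age_group = session$age_group,
    domain = session$domain,
    units = session$design$units,
    rule = session$params$rule,
    passed_training = session$passed_training,
    sigma_V = f_V$threshold, sigma_V_se = f_V$threshold_se,
    sigma_A = f_A$threshold, sigma_A_se = f_A$threshold_se,
    sigma_bimodal = fits$pooled_bimodal$threshold,
    sigma_bimodal_se = fits$pooled_bimodal$threshold_se,
    sigma_pred = pred$sigma_VA,
    w_V_thresholds = pred$weights$w_V,
    w_A_thresholds = pred$weights$w_A,
    slope = sl$slope, slope_se = sl$slope_se,
    w_A_slope = w_slope$w_A,
    w_A_slope_in_range = w_slope$in_range,
    all_converged = all(vapply(fits$fits, `[[`, logical(1L), "converged"))
  )
  structure(list(observer = observer, pses = pses, fits = fits,
                 slope = sl, prediction = pred),
            class = "observer_analysis")
}

#' Cohort configuration
#'
#' A cohort is a set of age groups, each with its own observer model, run
#' on one task domain. [default_cohort()] builds the stock developmental
#' cohort: younger groups dominated by a single modality (auditory capture
#' in time, visual capture in space — the developmental signature), an
#' optimally integrating adult group, and unimodal noise shrinking with
#' age.
#'
#' @param domain `"time"` or `"space"`.
#' @param groups list of group descriptors; each a list with `age_group`,
#'   `n`, `rule`, `sigma_V`, `sigma_A`, optional `w_A_fixed`, `lapse`.
#' @param design a [bisection_design()] (defaults to the stock design for
#'   `domain`).
#' @param n_boot bootstrap replicates per fit.
#' @param seed root integer seed; every observer's seed is derived from it.
#' @param recenter,weighted_regression analysis options (see
#'   [pooled_bimodal_threshold()], [slope_from_pses()]).
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(domain, groups, design = NULL, n_boot = 100L,
                          seed = 1L, recenter = TRUE,
                          weighted_regression = FALSE) {
  domain <- match.arg(domain, c("time", "space"))
  if (is.null(design)) design <- bisection_design(domain)
  stopifnot(inherits(design, "bisection_design"), design$domain == domain,
            is.list(groups), length(groups) >= 1L)
  n_obs <- sum(vapply(groups, function(g) as.integer(g$n), integer(1L)))
  if (n_obs < 1L) stop("cohort contains no observers", call. = FALSE)
  for (g in groups) {
    stopifnot(!is.null(g$age_group), !is.null(g$n), g$n >= 0,
              !is.null(g$rule), !is.null(g$sigma_V), !is.null(g$sigma_A))
  }
  structure(list(domain = domain, groups = groups, design = design,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 recenter = recenter,
                 weighted_regression = weighted_regression),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param n_per_group observers per age group in the stock cohort.
#' @export
default_cohort <- function(domain = c("time", "space"), n_per_group = 10L,
                           seed = 1L, n_boot = 100L) {
  domain <- match.arg(domain)
  groups <- if (domain == "time") {
    # ms; auditory precision improves fastest, audition captures time in
    # childhood, adults integrate
    list(
      list(age_group = "6y",     n = n_per_group, rule = "auditory_capture",
           sigma_V = 160, sigma_A = 150),
      list(age_group = "8-9y",   n = n_per_group, rule = "auditory_capture",
           sigma_V = 130, sigma_A = 110),
      list(age_group = "10-12y", n = n_per_group, rule = "auditory_capture",
           sigma_V = 110, sigma_A = 95),
      list(age_group = "adult",  n = n_per_group, rule = "optimal",
           sigma_V = 120, sigma_A = 70)
    )
  } else {
    # deg; vision captures space in childhood, adults integrate
    list(
      list(age_group = "6y",     n = n_per_group, rule = "visual_capture",
           sigma_V = 7,   sigma_A = 8),
      list(age_group = "8-9y",   n = n_per_group, rule = "visual_capture",
           sigma_V = 5,   sigma_A = 8),
      list(age_group = "10-12y", n = n_per_group, rule = "visual_capture",
           sigma_V = 4.5, sigma_A = 6),
      list(age_group = "adult",  n = n_per_group, rule = "optimal",
           sigma_V = 2.5, sigma_A = 8)
    )
  }
  cohort_config(domain, groups, seed = seed, n_boot = n_boot)
}

#' Run the full simulate-fit-combine-evaluate pipeline
#'
#' Simulates every observer of a cohort, fits all conditions, computes
#' per-observer weights and predictions, and aggregates by age group.
#' Failures (e.g. a non-converging fit for one observer) are reported and
#' skipped; the pipeline continues with the remaining observers.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory: if given, writes `trials.csv`,
#'   `fits.csv`, `pses.csv`, `observers.csv`, `group_summary.csv` and a
#'   `manifest.json` with the configuration and seeds.
#' @param progress print one line per observer.
#' @return List of class `"pipeline_result"`: `trials`, `fit_table`,
#'   `observers`, `pses`, `groups` (see [aggregate_by_age()]),
#'   `failures` (named list of error messages), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  trials <- list(); fit_tabs <- list(); obs_rows <- list(); pse_tabs <- list()
  failures <- list()
  for (g in config$groups) {
    for (i in seq_len(g$n)) {
      id <- sprintf("%s_%02d", gsub("[^0-9A-Za-z]+", "", g$age_group), i)
      obs_seed <- derive_seed_(config$seed, paste0(config$domain, ":", id))
      params <- observer_params(
        sigma_V = g$sigma_V, sigma_A = g$sigma_A, rule = g$rule,
        w_A_fixed = if (is.null(g$w_A_fixed)) NA_real_ else g$w_A_fixed,
        lapse = if (is.null(g$lapse)) 0 else g$lapse,
        seed = obs_seed)
      res <- tryCatch({
        sess <- simulate_session(params, config$design, observer_id = id,
                                 age_group = g$age_group)
        ana <- analyze_observer(sess, n_boot = config$n_boot,
                                seed = derive_seed_(obs_seed, "boot"),
                                weighted_regression = config$weighted_regression)
        list(sess = sess, ana = ana)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[id]] <- conditionMessage(res)
        if (progress) message(sprintf("  %s: FAILED (%s)", id, failures[[id]]))
        next
      }
      trials[[id]] <- res$sess$trials
      fit_tabs[[id]] <- res$ana$fits$table
      obs_rows[[id]] <- res$ana$observer
      pse_tabs[[id]] <- res$ana$pses
      if (progress) message(sprintf("  %s: ok", id))
    }
  }
  if (length(obs_rows) == 0L) {
    stop("pipeline produced no analysable observers", call. = FALSE)
  }
  observers <- do.call(rbind, obs_rows)
  pses <- do.call(rbind, pse_tabs)
  rownames(observers) <- rownames(pses) <- NULL
  groups <- aggregate_by_age(observers, pses)
  result <- structure(list(
    trials = do.call(rbind, trials),
    fit_table = do.call(rbind, fit_tabs),
    observers = observers, pses = pses, groups = groups,
    failures = failures, config = config
  ), class = "pipeline_result")
  rownames(result$trials) <- rownames(result$fit_table) <- NULL
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s domain: %d observers (%d failed), %d trials\n",
              x$config$domain, nrow(x$observers), length(x$failures),
              nrow(x$trials)))
  print(x$groups$summary[, c("age_group", "n", "sigma_bimodal", "sigma_pred",
                             "w_A_thresholds", "w_A_slope")])
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' @param result a `"pipeline_result"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(result$fit_table, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pses, file.path(out_dir, "pses.csv"),
                   row.names = FALSE)
  utils::write.csv(result$observers, file.path(out_dir, "observers.csv"),
                   row.names = FALSE)
  utils::write.csv(result$groups$summary,
                   file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  manifest <- list(
    package = "avbisect",
    version = as.character(utils::packageVersion("avbisect")),
    r_version = as.character(getRversion()),
    domain = result$config$domain,
    seed = result$config$seed,
    n_boot = result$config$n_boot,
    groups = lapply(result$config$groups, function(g) {
      g[c("age_group", "n", "rule", "sigma_V", "sigma_A")]
    }),
    design = list(
      trials_per_condition = result$config$design$trials_per_condition,
      conflicts = result$config$design$conditions$conflict[
        result$config$design$conditions$condition == "bimodal"],
      second_onset_ms = result$config$design$second_onset_ms
    ),
    failures = result$failures
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read and write trial tables
#'
#' Trial tables are flat CSV files, one row per trial, with columns
#' `observer_id`, `age_group`, `domain`, `units`, `condition`, `conflict`,
#' `probe_offset`, `response` (UTF-8, '.' decimal separator). Reading
#' validates the schema and reports offending row numbers.
#'
#' @param trials a trial data frame (or `"bisection_session"`).
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the validated trial data frame.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "bisection_session")) trials <- trials$trials
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  needed <- c("observer_id", "age_group", "domain", "units", "condition",
              "conflict", "probe_offset", "response")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("trial file contains a header but no trials")
    return(tab)
  }
  bad_resp <- which(!(tab$response %in% c(0L, 1L)))
  if (length(bad_resp) > 0L) {
    stop(sprintf("non-binary response on row%s %s",
                 if (length(bad_resp) > 1L) "s" else "",
                 paste(utils::head(bad_resp, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad_cond <- which(!(tab$condition %in% c("visual", "auditory", "bimodal")))
  if (length(bad_cond) > 0L) {
    stop(sprintf("unknown condition label on row%s %s",
                 if (length(bad_cond) > 1L) "s" else "",
                 paste(utils::head(bad_cond, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad_x <- which(!is.finite(tab$probe_offset))
  if (length(bad_x) > 0L) {
    stop(sprintf("non-finite probe_offset on row%s %s",
                 if (length(bad_x) > 1L) "s" else "",
                 paste(utils::head(bad_x, 5L), collapse = ", ")),
         call. = FALSE)
  }
  tab
}
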