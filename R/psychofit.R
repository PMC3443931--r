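#' Maximum-likelihood cumulative-Gaussian fit
#'
#' Fits `P(response = 1 | x) = pnorm((x - pse) / threshold)` to raw binary
#' trials by maximizing the Bernoulli likelihood (no binning — adaptive
#' placements are uneven and unbinned), parameterized as
#' `(pse, log threshold)`. The optimizer starts from the probit-regression
#' closed form, so refits of identical data are identical. No lapse
#' parameter is fitted.
#'
#' @param trials data frame with numeric `probe_offset` and binary
#'   `response` columns (one row per trial).
#' @param condition,conflict labels stored in the result.
#' @param min_trials minimum number of trials required (default 20).
#' @return Object of class `"psychometric_fit"`: list with `pse`,
#'   `threshold`, `pse_se`, `threshold_se` (`NA` until [bootstrap_se()] is
#'   run), `n_trials`, `condition`, `conflict`, `converged`, `at_bound`,
#'   `loglik`.
#' @export
fit_cumulative_gaussian <- function(trials, condition = NA_character_,
                                    conflict = NA_real_, min_trials = 20L) {
  x <- trials$probe_offset
  r <- trials$response
  stopifnot(is.numeric(x), all(is.finite(x)), all(r %in% c(0L, 1L)))
  if (length(x) < min_trials) {
    stop(sprintf("need at least %d trials, got %d", min_trials, length(x)),
         call. = FALSE)
  }
  if (length(unique(r)) < 2L) {
    stop(sprintf(
      "cannot fit condition '%s' (conflict %s): all responses identical",
      condition, format(conflict)), call. = FALSE)
  }

  start <- probit_start_(x, r)
  spread <- max(stats::sd(x), diff(range(x)) / 4, .Machine$double.eps)
  lo <- log(spread * 1e-3)
  hi <- log(spread * 1e3)

  nll <- function(par) {
    z <- (x - par[1]) / exp(par[2])
    -sum(r * stats::pnorm(z, log.p = TRUE) +
         (1 - r) * stats::pnorm(-z, log.p = TRUE))
  }
  opt <- stats::optim(c(start$mu, min(max(log(start$sigma), lo), hi)), nll,
                      method = "L-BFGS-B",
                      lower = c(-Inf, lo), upper = c(Inf, hi),
                      control = list(maxit = 500L))
  sigma <- exp(opt$par[2])
  at_bound <- opt$par[2] <= lo + 1e-6 || opt$par[2] >= hi - 1e-6
  structure(list(
    pse = unname(opt$par[1]), threshold = unname(sigma),
    pse_se = NA_real_, threshold_se = NA_real_,
    n_trials = length(x), condition = condition, conflict = conflict,
    converged = opt$convergence == 0L && !at_bound,
    at_bound = at_bound, loglik = -opt$value
  ), class = "psychometric_fit")
}

# Closed-form start from probit regression: pnorm(a + b x) with
# a = -mu/sigma, b = 1/sigma.
probit_start_ <- function(x, r) {
  co <- tryCatch(
    suppressWarnings(stats::coef(stats::glm.fit(
      cbind(1, x), r, family = stats::binomial("probit")))),
    error = function(e) c(NA_real_, NA_real_))
  if (all(is.finite(co)) && co[2] > 0) {
    list(mu = -co[1] / co[2], sigma = 1 / co[2])
  } else {
    # degenerate or non-monotone start: centre between class means
    m1 <- mean(x[r == 1]); m0 <- mean(x[r == 0])
    list(mu = (m0 + m1) / 2, sigma = max(stats::sd(x), 1e-3))
  }
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> %s (conflict %s): PSE = %.3f +/- %s, sigma = %.3f +/- %s (n = %d%s)\n",
    x$condition, format(x$conflict), x$pse,
    ifelse(is.na(x$pse_se), "NA", sprintf("%.3f", x$pse_se)),
    x$threshold,
    ifelse(is.na(x$threshold_se), "NA", sprintf("%.3f", x$threshold_se)),
    x$n_trials, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Bootstrap standard errors for a psychometric fit
#'
#' Nonparametric case resampling: trials are resampled with replacement,
#' the cumulative Gaussian refitted per replicate, and the standard error
#' taken as the standard deviation of the replicate estimates (100
#' replicates by default). Replicates that fail to fit are dropped and
#' counted; more than 20% failures attaches a warning flag.
#'
#' @param trials the data frame the fit was computed from.
#' @param fit the [fit_cumulative_gaussian()] result for `trials`.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed optional integer seed for the resampling.
#' @return The fit with `pse_se` and `threshold_se` filled in, plus
#'   `n_boot`, `n_boot_failed`, `boot_unreliable` (failure rate > 20%) and
#'   `boot_degenerate` (`n_boot < 2`).
#' @export
bootstrap_se <- function(trials, fit, n_boot = 100L, seed = NULL) {
  stopifnot(inherits(fit, "psychometric_fit"), n_boot >= 1L)
  if (!fit$converged) {
    stop("bootstrap requires a converged fit on the full data", call. = FALSE)
  }
  n <- nrow(trials)
  with_seed_(seed, {
    est <- matrix(NA_real_, n_boot, 2L)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(
        fit_cumulative_gaussian(trials[idx, , drop = FALSE],
                                fit$condition, fit$conflict,
                                min_trials = 1L),
        error = function(e) NULL)
      if (!is.null(fb) && fb$converged) est[b, ] <- c(fb$pse, fb$threshold)
    }
    ok <- stats::complete.cases(est)
    fit$n_boot <- n_boot
    fit$n_boot_failed <- sum(!ok)
    fit$boot_unreliable <- mean(!ok) > 0.2
    fit$boot_degenerate <- sum(ok) < 2L
    if (fit$boot_unreliable) {
      warning(sprintf("%d/%d bootstrap replicates failed to converge (%s)",
                      fit$n_boot_failed, n_boot, fit$condition))
    }
    fit$pse_se <- if (fit$boot_degenerate) 0 else stats::sd(est[ok, 1])
    fit$threshold_se <- if (fit$boot_degenerate) 0 else stats::sd(est[ok, 2])
    fit
  })
}

#' Bias-correct PSEs by the zero-conflict condition
#'
#' Bisection responses carry constant biases of no interest here (e.g. the
#' first interval tends to appear longer); they are removed by subtracting
#' the zero-conflict PSE from every conflict condition's PSE, so the
#' zero-conflict entry is 0 by construction.
#'
#' @param fits list of `"psychometric_fit"` objects for the bimodal
#'   conditions, one per conflict level, including conflict 0.
#' @return Data frame with columns `conflict`, `pse_corrected`, `pse_se`.
#' @export
bias_correct <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1L), "psychometric_fit")))
  conflicts <- vapply(fits, `[[`, numeric(1L), "conflict")
  i0 <- which(conflicts == 0)
  if (length(i0) != 1L) {
    stop("bias correction requires exactly one zero-conflict fit",
         call. = FALSE)
  }
  pse0 <- fits[[i0]]$pse
  data.frame(
    conflict = conflicts,
    pse_corrected = vapply(fits, `[[`, numeric(1L), "pse") - pse0,
    pse_se = vapply(fits, `[[`, numeric(1L), "pse_se")
  )
}

#' Pooled bimodal threshold across all conflict conditions
#'
#' All conflict conditions contribute to the two-cue threshold estimate:
#' each condition's trials are recentred on that condition's fitted PSE
#' (removing the conflict-dependent PSE shifts that would otherwise
#' inflate the pooled slope estimate), the recentred trials are pooled,
#' and a single cumulative Gaussian with mean constrained to 0 is fitted,
#' returning the pooled threshold with a bootstrap SE (resampling within
#' condition). Set `recenter = FALSE` to pool raw trials and fit both
#' parameters instead.
#'
#' @param trials_by_conflict named list of trial data frames, one per
#'   bimodal conflict level.
#' @param fits matching list of converged `"psychometric_fit"` objects.
#' @param n_boot bootstrap replicates for the SE (default 100; 0 skips).
#' @param seed optional integer seed.
#' @param recenter recentre each condition on its own PSE (default TRUE).
#' @return A `"psychometric_fit"` with `condition = "bimodal_pooled"`,
#'   `pse` fixed at 0 when recentred, and the pooled `threshold`.
#' @export
pooled_bimodal_threshold <- function(trials_by_conflict, fits,
                                     n_boot = 100L, seed = NULL,
                                     recenter = TRUE) {
  stopifnot(length(trials_by_conflict) == length(fits), length(fits) >= 1L)
  centres <- vapply(fits, `[[`, numeric(1L), "pse")
  # the recentring needs only each condition's PSE, which stays
  # identifiable even when a condition's own slope estimate hit a bound
  bad <- !is.finite(centres)
  if (any(bad)) {
    stop(sprintf("unusable bimodal fit at conflict %s",
                 paste(vapply(fits[bad], `[[`, numeric(1L), "conflict"),
                       collapse = ", ")), call. = FALSE)
  }
  recentred <- Map(function(tr, c0) {
    tr$probe_offset <- tr$probe_offset - if (recenter) c0 else 0
    tr
  }, trials_by_conflict, centres)

  fit_pooled <- function(trs) {
    pooled <- do.call(rbind, trs)
    if (recenter) {
      sigma <- fit_sigma_only_(pooled$probe_offset, pooled$response)
      list(pse = 0, threshold = sigma)
    } else {
      f <- fit_cumulative_gaussian(pooled, "bimodal_pooled", NA_real_)
      list(pse = f$pse, threshold = f$threshold)
    }
  }

  full <- fit_pooled(recentred)
  th_se <- NA_real_
  if (n_boot > 0L) {
    th_se <- with_seed_(seed, {
      reps <- vapply(seq_len(n_boot), function(b) {
        res <- lapply(recentred, function(tr) {
          tr[sample.int(nrow(tr), nrow(tr), replace = TRUE), , drop = FALSE]
        })
        tryCatch(fit_pooled(res)$threshold, error = function(e) NA_real_)
      }, numeric(1L))
      if (sum(!is.na(reps)) < 2L) 0 else stats::sd(reps, na.rm = TRUE)
    })
  }
  structure(list(
    pse = full$pse, threshold = full$threshold,
    pse_se = if (recenter) 0 else NA_real_, threshold_se = th_se,
    n_trials = sum(vapply(trials_by_conflict, nrow, integer(1L))),
    condition = "bimodal_pooled", conflict = NA_real_,
    converged = TRUE, at_bound = FALSE, loglik = NA_real_
  ), class = "psychometric_fit")
}

# 1-D ML fit of the threshold with the mean pinned at 0.
fit_sigma_only_ <- function(x, r) {
  stopifnot(length(unique(r)) == 2L)
  spread <- max(stats::sd(x), .Machine$double.eps)
  nll <- function(ls) {
    z <- x / exp(ls)
    -sum(r * stats::pnorm(z, log.p = TRUE) +
         (1 - r) * stats::pnorm(-z, log.p = TRUE))
  }
  opt <- stats::optimize(nll, c(log(spread * 1e-3), log(spread * 1e3)))
  exp(opt$minimum)
}

#' Fit every condition of a simulated session
#'
#' Convenience wrapper running [fit_cumulative_gaussian()] +
#' [bootstrap_se()] per condition x conflict cell of a session's trial
#' table, plus [pooled_bimodal_threshold()] across the bimodal conflicts.
#'
#' @param session a `"bisection_session"` (or any data frame with the same
#'   trial columns).
#' @param n_boot bootstrap replicates per fit (default 100).
#' @param seed optional integer seed for all bootstraps.
#' @return List of class `"session_fits"` with elements `fits` (named list
#'   of `"psychometric_fit"`, names like `"visual"`, `"bimodal@-50"`),
#'   `pooled_bimodal` (the pooled fit), `table` (one row per fit), and the
#'   session labels.
#' @export
fit_session <- function(session, n_boot = 100L, seed = NULL) {
  trials <- if (inherits(session, "bisection_session")) session$trials else session
  cells <- unique(trials[, c("condition", "conflict")])
  cells <- cells[order(cells$condition, cells$conflict), ]
  fits <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- trials[trials$condition == cells$condition[i] &
                  trials$conflict == cells$conflict[i], , drop = FALSE]
    key <- if (cells$condition[i] == "bimodal") {
      sprintf("bimodal@%g", cells$conflict[i])
    } else {
      cells$condition[i]
    }
    f <- fit_cumulative_gaussian(sub, cells$condition[i], cells$conflict[i])
    if (f$converged && n_boot > 0L) {
      f <- bootstrap_se(sub, f, n_boot = n_boot,
                        seed = if (is.null(seed)) NULL else derive_seed_(seed, key))
    }
    fits[[key]] <- f
  }
  bi_keys <- grep("^bimodal@", names(fits), value = TRUE)
  bi_trials <- lapply(bi_keys, function(k) {
    d <- fits[[k]]$conflict
    trials[trials$condition == "bimodal" & trials$conflict == d, , drop = FALSE]
  })
  pooled <- pooled_bimodal_threshold(
    bi_trials, fits[bi_keys], n_boot = n_boot,
    seed = if (is.null(seed)) NULL else derive_seed_(seed, "pooled"))

  tab <- do.call(rbind, lapply(c(fits, list(bimodal_pooled = pooled)), function(f) {
    data.frame(condition = f$condition, conflict = f$conflict,
               n_trials = f$n_trials, pse = f$pse, pse_se = f$pse_se,
               threshold = f$threshold, threshold_se = f$threshold_se,
               converged = f$converged)
  }))
  rownames(tab) <- NULL
  if (inherits(session, "bisection_session")) {
    tab <- cbind(data.frame(observer_id = session$observer_id,
                            age_group = session$age_group,
                            domain = session$domain,
                            units = session$design$units), tab)
  }
  structure(list(fits = fits, pooled_bimodal = pooled, table = tab,
                 observer_id = if (inherits(session, "bisection_session"))
                   session$observer_id else NA_character_),
            class = "session_fits")
}
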