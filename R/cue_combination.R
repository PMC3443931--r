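#' MLE-predicted bimodal threshold
#'
#' Under maximum-likelihood (reliability-weighted) integration the bimodal
#' variance is the harmonic combination of the unimodal variances,
#' `sigma_VA^2 = sigma_V^2 sigma_A^2 / (sigma_V^2 + sigma_A^2)`, never
#' larger than the better single cue and at best a factor `sqrt(2)` better
#' (when the two cues are equally reliable).
#'
#' @param sigma_V,sigma_A positive unimodal thresholds.
#' @return The predicted bimodal threshold (same units).
#' @examples
#' predict_bimodal_sigma(1, 1) * sqrt(2)  # 1
#' predict_bimodal_sigma(3, 4)            # 2.4
#' @export
predict_bimodal_sigma <- function(sigma_V, sigma_A) {
  stopifnot(is.numeric(sigma_V), is.numeric(sigma_A),
            all(sigma_V > 0), all(sigma_A > 0))
  sigma_V * sigma_A / sqrt(sigma_V^2 + sigma_A^2)
}

#' Cue weights from unimodal thresholds
#'
#' Weights are inversely proportional to the unimodal variances:
#' `w_V = sigma_A^2 / (sigma_A^2 + sigma_V^2)`, and `w_A = 1 - w_V` so the
#' pair sums to one exactly.
#'
#' @param sigma_V,sigma_A positive unimodal thresholds.
#' @return A `"weight_set"`: list with `w_V`, `w_A`,
#'   `source = "thresholds"`, `in_range = TRUE`.
#' @examples
#' weights_from_thresholds(1, 2)  # w_V = 0.8, w_A = 0.2
#' @export
weights_from_thresholds <- function(sigma_V, sigma_A) {
  stopifnot(is.numeric(sigma_V), length(sigma_V) == 1L, sigma_V > 0,
            is.numeric(sigma_A), length(sigma_A) == 1L, sigma_A > 0)
  w_V <- sigma_A^2 / (sigma_A^2 + sigma_V^2)
  structure(list(w_V = w_V, w_A = 1 - w_V, source = "thresholds",
                 in_range = TRUE),
            class = "weight_set")
}

#' Cue weights from the PSE-versus-conflict slope
#'
#' In the symmetric conflict frame the predicted PSE is
#' `(1 - 2 w_A) * delta`, so its slope in `delta` is `1 - 2 w_A` and
#' `w_A = (1 - slope) / 2`. Slopes outside `[-1, 1]` give weights outside
#' `[0, 1]`; these are preserved (clipping would bias group comparisons of
#' the two weight estimates) and flagged via `in_range = FALSE`.
#'
#' @param slope fitted slope of bias-corrected PSE on conflict (a
#'   [slope_from_pses()] result or a bare number).
#' @return A `"weight_set"` with `source = "pse_slope"`.
#' @examples
#' weights_from_slope(1)$w_A   # 0: full visual dominance
#' weights_from_slope(-1)$w_A  # 1: full auditory dominance
#' @export
weights_from_slope <- function(slope) {
  if (inherits(slope, "slope_estimate")) slope <- slope$slope
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  w_A <- (1 - slope) / 2
  structure(list(w_V = 1 - w_A, w_A = w_A, source = "pse_slope",
                 in_range = w_A >= 0 && w_A <= 1),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> w_V = %.3f, w_A = %.3f (from %s%s)\n",
              x$w_V, x$w_A, x$source,
              if (x$in_range) "" else ", OUT OF [0,1]"))
  invisible(x)
}

#' Predicted PSE under cue conflict
#'
#' In the symmetric parametrization the visual and auditory standards are
#' displaced by `+delta` and `-delta` from the neutral midpoint, so the
#' weighted-average percept sits at
#' `S(delta) = w_V * delta - w_A * delta = (1 - 2 w_A) * delta`:
#' `+delta` under full visual dominance, `-delta` under full auditory
#' dominance, 0 for balanced weights. Temporal conflicts are stored as
#' half-conflicts and are already on this symmetric abscissa after
#' [conflict_pse()] symmetrization.
#'
#' @param weights a `"weight_set"` (either source).
#' @param conflict conflict level(s) `delta` (ms half-conflict or deg).
#' @return Predicted PSE(s) in the symmetric frame.
#' @export
predict_pse <- function(weights, conflict) {
  stopifnot(inherits(weights, "weight_set"), is.numeric(conflict))
  (1 - 2 * weights$w_A) * conflict
}

#' Bias-corrected PSEs in the symmetric conflict frame
#'
#' Maps fitted (raw) bimodal PSEs to the frame in which the two cue
#' standards sit symmetrically at `±delta` about the neutral midpoint —
#' the frame of [predict_pse()] and the conflict-slope weight estimate, in
#' which full visual dominance has slope +1 and full auditory dominance
#' slope -1 in both task domains.
#'
#' After subtracting the zero-conflict PSE ([bias_correct()]):
#' * time — the conflict geometry is asymmetric (visual components fixed,
#'   auditory midpoint shifted by `-delta`), so the neutral midpoint lies
#'   at `-delta` and the corrected PSE is re-centred by `+delta`;
#' * space — the geometry is already symmetric, but a probe that *nulls* a
#'   `+delta` visual displacement sits at `-delta`, so the perceived shift
#'   of the standard is the negative of the fitted probe-axis PSE.
#'
#' @param fits list of bimodal `"psychometric_fit"` objects across
#'   conflicts (including conflict 0), or a [bias_correct()] data frame.
#' @param domain `"time"` or `"space"`.
#' @return Data frame with `conflict`, `pse_corrected` (symmetric frame),
#'   `pse_se`.
#' @export
conflict_pse <- function(fits, domain = c("time", "space")) {
  domain <- match.arg(domain)
  corr <- if (is.data.frame(fits)) fits else bias_correct(fits)
  stopifnot(all(c("conflict", "pse_corrected") %in% names(corr)))
  if (domain == "time") {
    corr$pse_corrected <- corr$pse_corrected + corr$conflict
  } else {
    corr$pse_corrected <- -corr$pse_corrected
  }
  corr
}

#' Slope of PSE against conflict
#'
#' Ordinary least-squares regression of the (bias-corrected, symmetric
#' frame) PSEs on the conflict levels — the per-observer slope whose value
#' is +1 under total visual dominance, -1 under total auditory dominance,
#' and `1 - 2 w_A` for a weighted averager.
#'
#' @param points data frame with `conflict` and `pse_corrected` columns
#'   (a [conflict_pse()] result).
#' @param weighted if `TRUE`, inverse-variance weights from `pse_se^2` are
#'   used (requires finite positive `pse_se`); default unweighted.
#' @return Object of class `"slope_estimate"`: `slope`, `intercept`,
#'   `slope_se`, `n_points`.
#' @export
slope_from_pses <- function(points, weighted = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("conflict", "pse_corrected") %in% names(points)))
  d <- points$conflict
  s <- points$pse_corrected
  if (length(unique(d)) < 2L) {
    stop("need at least two distinct conflict levels", call. = FALSE)
  }
  w <- if (weighted) {
    se <- points$pse_se
    stopifnot(all(is.finite(se)), all(se > 0))
    1 / se^2
  } else {
    rep(1, length(d))
  }
  fit <- stats::lm.wfit(cbind(1, d), s, w)
  res <- fit$residuals
  dfree <- length(d) - 2L
  xc <- d - sum(w * d) / sum(w)
  slope_se <- if (dfree > 0L) {
    sqrt(sum(w * res^2) / dfree / sum(w * xc^2))
  } else {
    NA_real_
  }
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 slope_se = slope_se, n_points = length(d)),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope_estimate> slope = %.3f +/- %s (n = %d)\n",
              x$slope,
              ifelse(is.na(x$slope_se), "NA", sprintf("%.3f", x$slope_se)),
              x$n_points))
  invisible(x)
}

#' Full MLE prediction for one observer
#'
#' Bundles the integration model's predictions given fitted unimodal
#' thresholds: the predicted bimodal threshold, the threshold-derived
#' weights, and the predicted PSE at each conflict level of a design.
#'
#' @param sigma_V,sigma_A fitted unimodal thresholds.
#' @param conflicts conflict levels to predict PSEs at.
#' @return List of class `"mle_prediction"`: `sigma_VA`, `weights`
#'   (threshold source), `predicted_pse` (data frame `conflict`, `pse`).
#' @export
mle_prediction <- function(sigma_V, sigma_A, conflicts = numeric()) {
  w <- weights_from_thresholds(sigma_V, sigma_A)
  structure(list(
    sigma_VA = predict_bimodal_sigma(sigma_V, sigma_A),
    weights = w,
    predicted_pse = data.frame(conflict = conflicts,
                               pse = predict_pse(w, conflicts))
  ), class = "mle_prediction")
}

#' @export
print.mle_prediction <- function(x, ...) {
  cat(sprintf("<mle_prediction> sigma_VA = %.3f, w_V = %.3f, w_A = %.3f\n",
              x$sigma_VA, x$weights$w_V, x$weights$w_A))
  invisible(x)
}
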