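#' QUEST-style adaptive track for the bisection point
#'
#' A Bayesian adaptive procedure that maintains a posterior over the
#' observer's point of subjective bisection and recommends placing the
#' next trial at the posterior mean (QUEST+ convention; the posterior mode
#' is available as an option). The likelihood of a "closer to third"
#' response at probe offset `x` given candidate bisection point `m` is the
#' cumulative Gaussian `pnorm((x - m) / assumed_slope)`.
#'
#' Each placement adds zero-centred Gaussian jitter (`jitter_sd`) to the
#' recommendation, so the psychometric function is sampled densely near
#' the bisection point but still out onto its flanks — good for estimating
#' both the PSE and the slope — and, because the jitter is centred, the
#' two responses remain equally likely on average.
#'
#' @param prior_mean prior mean of the bisection point (ms or deg).
#' @param prior_sd positive prior SD; the grid spans `prior_mean ± 4 * prior_sd`.
#' @param assumed_slope positive SD of the assumed cumulative-Gaussian
#'   psychometric function.
#' @param jitter_sd nonnegative SD of the placement jitter.
#' @param grid_n number of grid points (default 201).
#' @return An object of class `"quest_track"`: list with `grid`,
#'   `log_post`, `assumed_slope`, `jitter_sd`, `n_updates`.
#' @export
quest_track <- function(prior_mean, prior_sd, assumed_slope,
                        jitter_sd = 0, grid_n = 201L) {
  stopifnot(is.finite(prior_mean), prior_sd > 0, assumed_slope > 0,
            jitter_sd >= 0, grid_n >= 3L)
  half_span <- max(4 * prior_sd, 3 * assumed_slope)
  grid <- seq(prior_mean - half_span, prior_mean + half_span,
              length.out = as.integer(grid_n))
  log_post <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  log_post <- log_post - log(sum(exp(log_post - max(log_post))) ) - max(log_post)
  structure(list(grid = grid, log_post = log_post,
                 assumed_slope = assumed_slope, jitter_sd = jitter_sd,
                 n_updates = 0L),
            class = "quest_track")
}

#' Update a track with one observed trial
#'
#' Adds the pointwise Bernoulli log-likelihood of the response to the log
#' posterior. Updates commute: any permutation of a set of trials yields
#' the same final posterior. Likelihood values are floored at 1e-10 so a
#' response far out on the "wrong" flank never produces `log(0)`.
#'
#' @param track a [quest_track()].
#' @param probe_offset the probe offset that was presented.
#' @param response observed binary response (1 = "closer to third").
#' @return The updated track.
#' @export
quest_update <- function(track, probe_offset, response) {
  stopifnot(inherits(track, "quest_track"), response %in% c(0L, 1L),
            is.finite(probe_offset))
  p1 <- stats::pnorm((probe_offset - track$grid) / track$assumed_slope)
  lik <- if (response == 1) p1 else 1 - p1
  track$log_post <- track$log_post + log(pmax(lik, 1e-10))
  # renormalize for numerical hygiene (does not change the recommendation)
  m <- max(track$log_post)
  track$log_post <- track$log_post - m - log(sum(exp(track$log_post - m)))
  track$n_updates <- track$n_updates + 1L
  track
}

#' Current recommendation of a track
#'
#' @param track a [quest_track()].
#' @param statistic `"mean"` (default) or `"mode"` of the posterior.
#' @return Scalar recommended probe offset.
#' @export
quest_recommendation <- function(track, statistic = c("mean", "mode")) {
  stopifnot(inherits(track, "quest_track"))
  statistic <- match.arg(statistic)
  w <- exp(track$log_post - max(track$log_post))
  w <- w / sum(w)
  if (statistic == "mean") sum(w * track$grid) else track$grid[which.max(w)]
}

#' Next placement: recommendation plus Gaussian jitter
#'
#' @inheritParams quest_recommendation
#' @return Scalar probe offset (drawn from the current RNG stream).
#' @export
quest_placement <- function(track, statistic = c("mean", "mode")) {
  rec <- quest_recommendation(track, statistic)
  rec + stats::rnorm(1L, 0, track$jitter_sd)
}

#' @export
print.quest_track <- function(x, ...) {
  cat(sprintf("<quest_track> %d updates, recommendation %.3f (grid %.1f..%.1f, %d pts)\n",
              x$n_updates, quest_recommendation(x), min(x$grid), max(x$grid),
              length(x$grid)))
  invisible(x)
}
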