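#' Bisection task designs
#'
#' A design describes one session of the audio-visual bisection experiment:
#' which conditions are interleaved, how many trials each receives, the
#' conflict levels of the bimodal conditions, and the nominal stimulus
#' timing. Two stock designs are provided:
#'
#' * `"time"` — temporal bisection: three stimuli over 1000 ms, the observer
#'   judges whether the second is closer in time to the first or the third.
#'   Five interleaved conditions (vision, audition, and three bimodal
#'   conflicts). The bimodal conflict is stored as the *half-conflict*
#'   `delta` applied to the second stimulus (auditory component at
#'   `+delta` ms relative to visual); the outer stimuli carry the opposite
#'   offset (`-delta`), so the effective audio-visual separation of the
#'   second stimulus from the outer pair is `2*delta`.
#' * `"space"` — spatial bisection along a speaker array: three stimuli, the
#'   second always 500 ms after the first, judged closer in space to the
#'   first or third. Seven interleaved conditions (vision, audition, five
#'   bimodal conflicts). The conflict `delta` is the displacement of the
#'   second stimulus' *visual* component (`+delta` deg) while its auditory
#'   component sits at `-delta`; the outer stimuli are audio-visually
#'   aligned.
#'
#' @param domain `"time"` or `"space"`.
#' @param conflicts signed conflict levels for the bimodal conditions
#'   (ms half-conflict for time, deg visual displacement for space).
#' @param trials_per_condition trials per interleaved condition.
#' @param units probe-offset units, `"ms"` or `"deg"` (derived from domain).
#' @return An object of class `"bisection_design"`: a list with elements
#'   `domain`, `units`, `conditions` (data frame with columns `condition`,
#'   `conflict`), `trials_per_condition`, `n_trials`, `total_duration_ms`,
#'   `second_onset_ms`, and the adaptive-track defaults `assumed_slope`,
#'   `jitter_sd`, `prior_sd`.
#' @examples
#' d <- bisection_design("time")
#' d$n_trials                      # 150
#' bisection_design("space")$second_onset_ms  # 500
#' @export
bisection_design <- function(domain = c("time", "space"),
                             conflicts = NULL,
                             trials_per_condition = 30L,
                             units = NULL) {
  domain <- match.arg(domain)
  if (is.null(conflicts)) {
    conflicts <- if (domain == "time") c(-50, 0, 50) else c(-9, -4.5, 0, 4.5, 9)
  }
  stopifnot(is.numeric(conflicts), all(is.finite(conflicts)),
            !anyDuplicated(conflicts))
  trials_per_condition <- as.integer(trials_per_condition)
  if (length(trials_per_condition) != 1L || is.na(trials_per_condition) ||
      trials_per_condition < 1L) {
    stop("`trials_per_condition` must be a positive integer", call. = FALSE)
  }
  if (is.null(units)) units <- if (domain == "time") "ms" else "deg"

  conditions <- rbind(
    data.frame(condition = c("visual", "auditory"), conflict = 0),
    data.frame(condition = "bimodal", conflict = sort(conflicts))
  )
  # QUEST defaults: assumed psychometric slope of the order of child
  # unimodal thresholds; jitter wide enough to sample both flanks.
  defaults <- if (domain == "time") {
    list(assumed_slope = 120, jitter_sd = 100)
  } else {
    list(assumed_slope = 15, jitter_sd = 10)
  }
  structure(list(
    domain = domain,
    units = units,
    conditions = conditions,
    trials_per_condition = trials_per_condition,
    n_trials = nrow(conditions) * trials_per_condition,
    total_duration_ms = 1000,
    second_onset_ms = 500,
    assumed_slope = defaults$assumed_slope,
    jitter_sd = defaults$jitter_sd,
    prior_sd = defaults$assumed_slope
  ), class = "bisection_design")
}

#' @export
print.bisection_design <- function(x, ...) {
  cat(sprintf("<bisection_design> %s domain (%s): %d conditions x %d trials = %d trials\n",
              x$domain, x$units, nrow(x$conditions), x$trials_per_condition,
              x$n_trials))
  cat("  conflicts:", paste(x$conditions$conflict[x$conditions$condition == "bimodal"],
                            collapse = ", "), x$units, "\n")
  invisible(x)
}

#' Specify a single bisection trial
#'
#' @param domain `"time"` or `"space"`.
#' @param condition `"visual"`, `"auditory"`, or `"bimodal"`.
#' @param conflict signed conflict `delta`; must be 0 unless bimodal.
#' @param probe_offset displacement `x` of the second stimulus from the
#'   physical midpoint of the first and third (ms or deg; positive towards
#'   the third stimulus).
#' @return A list of class `"trial_spec"`.
#' @export
trial_spec <- function(domain, condition, conflict = 0, probe_offset = 0) {
  domain <- match.arg(domain, c("time", "space"))
  condition <- match.arg(condition, c("visual", "auditory", "bimodal"))
  stopifnot(is.numeric(conflict), length(conflict) == 1L, is.finite(conflict),
            is.numeric(probe_offset), length(probe_offset) == 1L,
            is.finite(probe_offset))
  if (condition != "bimodal" && conflict != 0) {
    stop("unimodal conditions carry no audio-visual conflict", call. = FALSE)
  }
  structure(list(domain = domain, condition = condition,
                 conflict = conflict, probe_offset = probe_offset),
            class = "trial_spec")
}

#' Per-cue displacement of the second stimulus
#'
#' Returns the displacement of the second stimulus relative to each cue's
#' *own* midpoint — the midpoint of that cue's first and third stimuli.
#' This is the quantity an observer relying on that cue alone would judge.
#'
#' Geometry: in the temporal task the conflict `delta` shifts the second
#' stimulus' auditory component by `+delta` and the *outer* auditory stimuli
#' by `-delta`, so the auditory midpoint moves to `-delta` and the auditory
#' displacement is `x + 2*delta`; the visual components are unshifted, so
#' the visual displacement is `x`. In the spatial task the outer stimuli
#' are aligned and the second stimulus' visual/auditory components sit at
#' `x + delta` / `x - delta`.
#'
#' @param spec a [trial_spec()].
#' @return Named numeric vector `c(offset_V =, offset_A =)`.
#' @examples
#' cue_offsets(trial_spec("time", "bimodal", 50, 0))    # (0, 100)
#' cue_offsets(trial_spec("space", "bimodal", 4.5, 0))  # (4.5, -4.5)
#' @export
cue_offsets <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  x <- spec$probe_offset
  d <- spec$conflict
  if (spec$domain == "time") {
    c(offset_V = x, offset_A = x + 2 * d)
  } else {
    c(offset_V = x + d, offset_A = x - d)
  }
}
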