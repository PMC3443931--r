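#' Parameterized bisection observer
#'
#' A generative observer is defined by its unimodal noise levels and a
#' combination rule for bimodal trials:
#'
#' * `"optimal"` — reliability-weighted averaging: weights from
#'   [weights_from_thresholds()] and bimodal noise from
#'   [predict_bimodal_sigma()] (the MLE integrator).
#' * `"visual_capture"` — the visual cue fully determines the percept
#'   (weights 1/0, bimodal noise `sigma_V`).
#' * `"auditory_capture"` — the auditory cue dominates (weights 0/1,
#'   bimodal noise `sigma_A`).
#' * `"fixed_weights"` — averaging with a fixed auditory weight
#'   `w_A_fixed`; bimodal noise `sqrt(w_V^2 sigma_V^2 + w_A^2 sigma_A^2)`.
#'
#' @param sigma_V,sigma_A positive unimodal thresholds (SD of the internal
#'   noise; ms for the temporal task, deg for the spatial task).
#' @param rule combination rule, see above.
#' @param w_A_fixed auditory weight in `[0, 1]`, used only for
#'   `rule = "fixed_weights"`.
#' @param lapse lapse rate in `[0, 0.1]`: proportion of trials answered at
#'   random regardless of the stimulus. Default 0 (the fitted model has no
#'   lapse term either).
#' @param seed integer seed making every simulation with these parameters
#'   reproducible, or `NULL` to draw from the current RNG stream.
#' @return A list of class `"observer_params"`.
#' @export
observer_params <- function(sigma_V, sigma_A,
                            rule = c("optimal", "visual_capture",
                                     "auditory_capture", "fixed_weights"),
                            w_A_fixed = NA_real_, lapse = 0, seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(sigma_V), length(sigma_V) == 1L, sigma_V > 0,
            is.numeric(sigma_A), length(sigma_A) == 1L, sigma_A > 0)
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse > 0.1) {
    stop("`lapse` must lie in [0, 0.1]", call. = FALSE)
  }
  if (rule == "fixed_weights" &&
      (!is.finite(w_A_fixed) || w_A_fixed < 0 || w_A_fixed > 1)) {
    stop("`w_A_fixed` must lie in [0, 1] for rule = \"fixed_weights\"",
         call. = FALSE)
  }
  structure(list(sigma_V = sigma_V, sigma_A = sigma_A, rule = rule,
                 w_A_fixed = w_A_fixed, lapse = lapse,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "observer_params")
}

#' Effective bimodal weights and noise of an observer
#'
#' @param params an [observer_params()].
#' @return List with `w_V`, `w_A`, `sigma_eff` for bimodal trials.
#' @keywords internal
effective_combination <- function(params) {
  switch(params$rule,
    optimal = {
      w <- weights_from_thresholds(params$sigma_V, params$sigma_A)
      list(w_V = w$w_V, w_A = w$w_A,
           sigma_eff = predict_bimodal_sigma(params$sigma_V, params$sigma_A))
    },
    visual_capture = list(w_V = 1, w_A = 0, sigma_eff = params$sigma_V),
    auditory_capture = list(w_V = 0, w_A = 1, sigma_eff = params$sigma_A),
    fixed_weights = {
      w_A <- params$w_A_fixed
      w_V <- 1 - w_A
      list(w_V = w_V, w_A = w_A,
           sigma_eff = sqrt(w_V^2 * params$sigma_V^2 +
                            w_A^2 * params$sigma_A^2))
    }
  )
}

#' Probability of a "closer to third" response
#'
#' The observer compares the perceived position (in time or space) of the
#' second stimulus with the perceived midpoint of the first and third. On
#' unimodal trials the relevant displacement is that cue's own offset (see
#' [cue_offsets()]); on bimodal trials it is the weighted combination
#' `w_V * offset_V + w_A * offset_A` under the observer's rule. The
#' response probability is
#' `lapse/2 + (1 - lapse) * pnorm(e / sigma_eff)`.
#'
#' @param spec a [trial_spec()].
#' @param params an [observer_params()].
#' @return Probability in `[0, 1]` that the response is 1
#'   ("second closer to third").
#' @examples
#' p <- observer_params(sigma_V = 1, sigma_A = 1, rule = "optimal")
#' s <- trial_spec("space", "bimodal", 0, probe_offset = sqrt(0.5))
#' response_probability(s, p)  # pnorm(1) = 0.841...
#' @export
response_probability <- function(spec, params) {
  stopifnot(inherits(spec, "trial_spec"), inherits(params, "observer_params"))
  off <- cue_offsets(spec)
  if (spec$condition == "visual") {
    e <- off[["offset_V"]]
    sigma_eff <- params$sigma_V
  } else if (spec$condition == "auditory") {
    e <- off[["offset_A"]]
    sigma_eff <- params$sigma_A
  } else {
    comb <- effective_combination(params)
    e <- comb$w_V * off[["offset_V"]] + comb$w_A * off[["offset_A"]]
    sigma_eff <- comb$sigma_eff
  }
  params$lapse / 2 + (1 - params$lapse) * stats::pnorm(e / sigma_eff)
}

#' Simulate one trial
#'
#' Bernoulli draw from [response_probability()], using the current RNG
#' stream (seed the stream, or use [simulate_session()], for
#' reproducibility).
#'
#' @inheritParams response_probability
#' @return Integer response: 1 = "second closer to third", 0 = "closer to
#'   first".
#' @export
simulate_trial <- function(spec, params) {
  p <- response_probability(spec, params)
  as.integer(stats::runif(1L) < p)
}

#' Simulate the training screen
#'
#' Mirrors the study's inclusion rule: ten maximally easy trials, with the
#' second stimulus far from the true midpoint, and a pass requires at least
#' `pass_threshold` correct. "Easy" defaults to `5 * max(sigma_V, sigma_A)`
#' so an attentive observer is essentially always correct.
#'
#' @param params an [observer_params()].
#' @param domain `"time"` or `"space"`.
#' @param n_trials number of training trials (default 10).
#' @param pass_threshold minimum correct to pass (default 7).
#' @param easy_offset magnitude of the probe offset used; default
#'   `5 * max(sigma_V, sigma_A)`.
#' @return List with `n_correct` and `passed`.
#' @export
simulate_training_screen <- function(params, domain = "time",
                                     n_trials = 10L, pass_threshold = 7L,
                                     easy_offset = NULL) {
  stopifnot(inherits(params, "observer_params"),
            n_trials >= pass_threshold, pass_threshold >= 0)
  if (is.null(easy_offset)) easy_offset <- 5 * max(params$sigma_V, params$sigma_A)
  side <- sample(c(-1, 1), n_trials, replace = TRUE)
  correct <- vapply(side, function(s) {
    # training runs unimodally (one visual, one auditory session); use the
    # poorer modality as the conservative screen
    cond <- if (params$sigma_V >= params$sigma_A) "visual" else "auditory"
    spec <- trial_spec(domain, cond, 0, s * easy_offset)
    resp <- simulate_trial(spec, params)
    resp == as.integer(s > 0)
  }, logical(1L))
  n_correct <- sum(correct)
  list(n_correct = n_correct, passed = n_correct >= pass_threshold)
}

#' Simulate a full bisection session
#'
#' Interleaves all conditions of `design` in randomized order, runs one
#' adaptive track per condition (so three or five simultaneous tracks in
#' the bimodal conflict conditions and one per unisensory condition),
#' places each trial at the track's recommendation plus zero-centred
#' Gaussian jitter, and draws responses from the observer model.
#'
#' @param params an [observer_params()]; its `seed` (if non-`NULL`) makes
#'   the whole session reproducible.
#' @param design a [bisection_design()].
#' @param observer_id,age_group labels carried into the trial table.
#' @param run_training if `TRUE`, the training screen is simulated first
#'   and its outcome stored as `passed_training`.
#' @return An object of class `"bisection_session"`: a list with
#'   `observer_id`, `age_group`, `domain`, `passed_training`, `params`,
#'   `design`, and `trials`, a data frame with one row per trial and
#'   columns `observer_id`, `age_group`, `domain`, `units`, `condition`,
#'   `conflict`, `probe_offset`, `response`.
#' @export
simulate_session <- function(params, design,
                             observer_id = "obs1", age_group = "adult",
                             run_training = TRUE) {
  stopifnot(inherits(params, "observer_params"),
            inherits(design, "bisection_design"))
  with_seed_(params$seed, {
    training <- if (run_training) {
      simulate_training_screen(params, design$domain)
    } else {
      list(n_correct = NA_integer_, passed = TRUE)
    }

    conds <- design$conditions
    n_cond <- nrow(conds)
    tracks <- lapply(seq_len(n_cond), function(i) {
      quest_track(prior_mean = 0, prior_sd = design$prior_sd,
                  assumed_slope = design$assumed_slope,
                  jitter_sd = design$jitter_sd)
    })

    order_idx <- sample(rep(seq_len(n_cond), each = design$trials_per_condition))
    n <- length(order_idx)
    probe <- numeric(n)
    resp <- integer(n)
    for (t in seq_len(n)) {
      i <- order_idx[t]
      x <- quest_placement(tracks[[i]])
      spec <- trial_spec(design$domain, conds$condition[i], conds$conflict[i], x)
      r <- simulate_trial(spec, params)
      tracks[[i]] <- quest_update(tracks[[i]], x, r)
      probe[t] <- x
      resp[t] <- r
    }

    trials <- data.frame(
      observer_id = observer_id,
      age_group = age_group,
      domain = design$domain,
      units = design$units,
      condition = conds$condition[order_idx],
      conflict = conds$conflict[order_idx],
      probe_offset = probe,
      response = resp,
      stringsAsFactors = FALSE
    )
    structure(list(observer_id = observer_id, age_group = age_group,
                   domain = design$domain,
                   passed_training = training$passed,
                   n_training_correct = training$n_correct,
                   params = params, design = design, trials = trials),
              class = "bisection_session")
  })
}

#' @export
print.bisection_session <- function(x, ...) {
  cat(sprintf("<bisection_session> %s (%s), %s domain: %d trials, training %s\n",
              x$observer_id, x$age_group, x$domain, nrow(x$trials),
              if (isTRUE(x$passed_training)) "passed" else "failed"))
  invisible(x)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state;
# NULL seed means "use the current stream".
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic child seed from a root seed and a string key; stays well
# inside the 32-bit integer range.
derive_seed_ <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(as.character(key))) h <- (h * 31 + c) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h * 97 + 1) %% .Machine$integer.max)
}
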