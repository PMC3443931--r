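#' Parameter-recovery experiment for the integration model
#'
#' Simulates optimally integrating observers with unimodal thresholds
#' drawn log-uniformly over four-fold ranges, runs each one through the
#' full session-simulation and fitting pipeline, and measures how well the
#' analysis recovers (a) the MLE-predicted bimodal threshold and (b) the
#' auditory weight, comparing the conflict-slope estimate with the
#' generating (variance-ratio) weight.
#'
#' The stock ranges are spatial-task thresholds spanning child to adult
#' precision (visual 2.5–10 deg, auditory 5–20 deg). The spatial design is
#' used because its five conflict levels out to ±9 deg give the
#' conflict-slope regression enough leverage relative to thresholds of
#' this size; the temporal design's ±50 ms span is small against
#' ~100 ms child thresholds, so weight recovery there needs more than 30
#' trials per condition.
#'
#' @param n_observers number of simulated observers (default 100).
#' @param domain task domain (default `"space"`).
#' @param sigma_V_range,sigma_A_range log-uniform sampling ranges for the
#'   unimodal thresholds.
#' @param trials_per_condition trials per interleaved condition.
#' @param n_boot bootstrap replicates for the pooled bimodal threshold SE.
#' @param seed root seed.
#' @return Data frame, one row per observer: true thresholds and weight,
#'   fitted pooled bimodal threshold with bootstrap SE, the predicted
#'   bimodal threshold from the true thresholds, the slope-derived
#'   auditory weight, plus the derived columns `sigma_z` (absolute
#'   deviation of the fitted from the predicted bimodal threshold in
#'   bootstrap-SE units) and `w_A_abs_err`.
#' @export
parameter_recovery <- function(n_observers = 100L, domain = "space",
                               sigma_V_range = c(2.5, 10),
                               sigma_A_range = c(5, 20),
                               trials_per_condition = 30L,
                               n_boot = 100L, seed = 1L) {
  design <- bisection_design(domain,
                             trials_per_condition = trials_per_condition)
  draws <- with_seed_(derive_seed_(seed, "recovery-draws"), {
    data.frame(
      sigma_V = exp(stats::runif(n_observers, log(sigma_V_range[1]),
                                 log(sigma_V_range[2]))),
      sigma_A = exp(stats::runif(n_observers, log(sigma_A_range[1]),
                                 log(sigma_A_range[2])))
    )
  })
  rows <- vector("list", n_observers)
  for (i in seq_len(n_observers)) {
    obs_seed <- derive_seed_(seed, paste0("recovery-obs-", i))
    params <- observer_params(draws$sigma_V[i], draws$sigma_A[i],
                              rule = "optimal", seed = obs_seed)
    row <- tryCatch({
      sess <- simulate_session(params, design, observer_id = sprintf("rec_%03d", i),
                               run_training = FALSE)
      fits <- fit_session(sess, n_boot = 0L)
      bi_keys <- grep("^bimodal@", names(fits$fits), value = TRUE)
      bi_trials <- lapply(fits$fits[bi_keys], function(f) {
        sess$trials[sess$trials$condition == "bimodal" &
                    sess$trials$conflict == f$conflict, , drop = FALSE]
      })
      pooled <- pooled_bimodal_threshold(
        bi_trials, fits$fits[bi_keys], n_boot = n_boot,
        seed = derive_seed_(obs_seed, "boot"))
      corr <- conflict_pse(fits$fits[bi_keys], domain)
      w_slope <- weights_from_slope(slope_from_pses(corr))
      w_true <- weights_from_thresholds(draws$sigma_V[i], draws$sigma_A[i])
      sigma_pred <- predict_bimodal_sigma(draws$sigma_V[i], draws$sigma_A[i])
      data.frame(
        observer = i,
        sigma_V_true = draws$sigma_V[i], sigma_A_true = draws$sigma_A[i],
        sigma_pred = sigma_pred,
        sigma_bimodal = pooled$threshold,
        sigma_bimodal_se = pooled$threshold_se,
        w_A_true = w_true$w_A, w_A_slope = w_slope$w_A,
        ok = TRUE
      )
    }, error = function(e) {
      data.frame(observer = i,
                 sigma_V_true = draws$sigma_V[i],
                 sigma_A_true = draws$sigma_A[i],
                 sigma_pred = NA_real_, sigma_bimodal = NA_real_,
                 sigma_bimodal_se = NA_real_,
                 w_A_true = NA_real_, w_A_slope = NA_real_, ok = FALSE)
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out$sigma_z <- abs(out$sigma_bimodal - out$sigma_pred) / out$sigma_bimodal_se
  out$w_A_abs_err <- abs(out$w_A_slope - out$w_A_true)
  out
}
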