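# Independent oracles used across the suite. These never call the code
# paths they check.

# Bernoulli trials at fixed placements from the cumulative-Gaussian model,
# bypassing the session machinery.
sim_trials <- function(n, mu, sigma, placements = NULL, spread = 2 * sigma) {
  x <- if (is.null(placements)) {
    stats::rnorm(n, mu, spread)
  } else {
    rep_len(placements, n)
  }
  data.frame(probe_offset = x,
             response = as.integer(stats::runif(n) < stats::pnorm((x - mu) / sigma)))
}

# Asymptotic SEs of (mu, sigma) from the observed Fisher information of the
# Bernoulli likelihood at the sampled placements, evaluated at the truth.
fisher_se <- function(x, mu, sigma) {
  z <- (x - mu) / sigma
  phi <- stats::dnorm(z)
  P <- stats::pnorm(z)
  w <- phi^2 / pmax(P * (1 - P), 1e-12)
  i11 <- sum(w) / sigma^2            # d/d mu
  i22 <- sum(w * z^2) / sigma^2      # d/d sigma
  i12 <- sum(w * z) / sigma^2
  info <- matrix(c(i11, i12, i12, i22), 2)
  se <- sqrt(diag(solve(info)))
  list(pse_se = se[1], threshold_se = se[2])
}

# Exhaustive 2-D grid search of the Bernoulli log-likelihood: the stated
# oracle for the ML psychometric fit.
grid_search_fit <- function(trials, mu_range, sigma_range,
                            n_mu = 161L, n_sigma = 161L) {
  x <- trials$probe_offset
  r <- trials$response
  mus <- seq(mu_range[1], mu_range[2], length.out = n_mu)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_sigma))
  best <- c(-Inf, NA, NA)
  for (s in sigmas) {
    zs <- outer(x, mus, function(xx, mm) (xx - mm) / s)
    ll <- colSums(r * stats::pnorm(zs, log.p = TRUE) +
                  (1 - r) * stats::pnorm(-zs, log.p = TRUE))
    j <- which.max(ll)
    if (ll[j] > best[1]) best <- c(ll[j], mus[j], s)
  }
  list(loglik = best[1], pse = best[2], threshold = best[3],
       mu_step = diff(mu_range) / (n_mu - 1),
       sigma_logstep = diff(log(sigma_range)) / (n_sigma - 1))
}

# Exact one-sample sign-flip permutation test (one-tailed, mean > 0):
# enumerates all 2^n sign assignments for small n.
perm_p_one_sample <- function(d) {
  n <- length(d)
  stopifnot(n <= 12)
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- signs %*% d / n
  mean(means >= obs - 1e-12)
}
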