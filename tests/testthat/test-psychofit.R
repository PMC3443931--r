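test_that("the ML fit recovers generating parameters on a large fixture", {
  set.seed(101)
  tr <- sim_trials(3000, mu = 10, sigma = 50, spread = 100)
  f <- fit_cumulative_gaussian(tr, "fixture")
  se <- fisher_se(tr$probe_offset, 10, 50)
  expect_true(f$converged)
  expect_lt(abs(f$pse - 10), 4 * se$pse_se)
  expect_lt(abs(f$threshold - 50), 4 * se$threshold_se)
  # spec-level sanity band for this fixture
  expect_gt(f$pse, 7); expect_lt(f$pse, 13)
  expect_gt(f$threshold, 45); expect_lt(f$threshold, 55)
})

test_that("mirror-symmetric data give a PSE of zero", {
  set.seed(3)
  half <- sim_trials(300, mu = 0, sigma = 20, spread = 40)
  mirrored <- rbind(half,
                    data.frame(probe_offset = -half$probe_offset,
                               response = 1L - half$response))
  f <- fit_cumulative_gaussian(mirrored, "mirror")
  expect_equal(f$pse, 0, tolerance = 1e-4)
})

test_that("refitting identical data is deterministic", {
  set.seed(17)
  tr <- sim_trials(200, 5, 30, spread = 60)
  f1 <- fit_cumulative_gaussian(tr)
  f2 <- fit_cumulative_gaussian(tr)
  expect_identical(f1$pse, f2$pse)
  expect_identical(f1$threshold, f2$threshold)
})

test_that("degenerate data are rejected with informative errors", {
  one_class <- data.frame(probe_offset = rnorm(30), response = rep(1L, 30))
  expect_error(fit_cumulative_gaussian(one_class, condition = "auditory"),
               "auditory.*identical")
  few <- sim_trials(10, 0, 1, spread = 3)
  expect_error(fit_cumulative_gaussian(few), "at least 20")
})

test_that("the fit is shift- and scale-equivariant", {
  set.seed(29)
  tr <- sim_trials(400, 8, 25, spread = 50)
  f0 <- fit_cumulative_gaussian(tr)
  sh <- tr; sh$probe_offset <- sh$probe_offset + 100
  fs <- fit_cumulative_gaussian(sh)
  expect_equal(fs$pse, f0$pse + 100, tolerance = 1e-3)
  expect_equal(fs$threshold, f0$threshold, tolerance = 1e-4)
  sc <- tr; sc$probe_offset <- sc$probe_offset * 3
  fk <- fit_cumulative_gaussian(sc)
  expect_equal(fk$pse, 3 * f0$pse, tolerance = 1e-3)
  expect_equal(fk$threshold, 3 * f0$threshold, tolerance = 1e-3)
})

test_that("the ML fit matches an exhaustive likelihood grid search", {
  set.seed(71)
  for (case in list(list(n = 120, mu = -5, sigma = 15),
                    list(n = 200, mu = 20, sigma = 60))) {
    placements <- seq(case$mu - 2.5 * case$sigma, case$mu + 2.5 * case$sigma,
                      length.out = 7)
    tr <- sim_trials(case$n, case$mu, case$sigma, placements = placements)
    f <- fit_cumulative_gaussian(tr)
    g <- grid_search_fit(tr,
                         mu_range = case$mu + c(-2, 2) * case$sigma,
                         sigma_range = case$sigma * c(0.2, 5))
    expect_lt(abs(f$pse - g$pse), 2 * g$mu_step)
    expect_lt(abs(log(f$threshold) - log(g$threshold)), 2 * g$sigma_logstep)
    expect_gte(f$loglik, g$loglik - 1e-6)  # ML never worse than the grid
  }
})

test_that("bootstrap SEs track the Fisher-information oracle", {
  set.seed(211)
  tr <- sim_trials(600, 10, 50, spread = 100)
  f <- fit_cumulative_gaussian(tr)
  f <- bootstrap_se(tr, f, n_boot = 100, seed = 12)
  se <- fisher_se(tr$probe_offset, 10, 50)
  expect_gt(f$pse_se, se$pse_se / 1.5)
  expect_lt(f$pse_se, se$pse_se * 1.5)
  expect_gt(f$threshold_se, se$threshold_se / 1.5)
  expect_lt(f$threshold_se, se$threshold_se * 1.5)
})

test_that("bootstrap SE shrinks like 1/sqrt(n) when trials double", {
  set.seed(313)
  tr1 <- sim_trials(500, 0, 40, spread = 80)
  tr2 <- rbind(tr1, sim_trials(500, 0, 40, spread = 80))
  f1 <- bootstrap_se(tr1, fit_cumulative_gaussian(tr1), n_boot = 200, seed = 1)
  f2 <- bootstrap_se(tr2, fit_cumulative_gaussian(tr2), n_boot = 200, seed = 2)
  expect_equal(f2$pse_se / f1$pse_se, 1 / sqrt(2), tolerance = 0.25)
})

test_that("a single bootstrap replicate is flagged degenerate with zero SE", {
  set.seed(5)
  tr <- sim_trials(100, 0, 10, spread = 20)
  f <- bootstrap_se(tr, fit_cumulative_gaussian(tr), n_boot = 1, seed = 1)
  expect_true(f$boot_degenerate)
  expect_identical(f$pse_se, 0)
})

test_that("bias correction subtracts the zero-conflict PSE", {
  mk <- function(pse, conflict) {
    structure(list(pse = pse, threshold = 1, pse_se = 0.1, threshold_se = 0.1,
                   n_trials = 30L, condition = "bimodal", conflict = conflict,
                   converged = TRUE, at_bound = FALSE, loglik = 0),
              class = "psychometric_fit")
  }
  fits <- list(mk(12, 0), mk(40, 50), mk(-10, -50))
  corr <- bias_correct(fits)
  expect_equal(corr$pse_corrected[corr$conflict == 0], 0)
  expect_equal(corr$pse_corrected[corr$conflict == 50], 28)
  expect_equal(corr$pse_corrected[corr$conflict == -50], -22)

  # translation invariance
  shifted <- lapply(fits, function(f) { f$pse <- f$pse + 7.3; f })
  expect_equal(bias_correct(shifted)$pse_corrected, corr$pse_corrected)

  # all equal PSEs -> all zero
  flat <- list(mk(5, 0), mk(5, 50), mk(5, -50))
  expect_true(all(bias_correct(flat)$pse_corrected == 0))

  expect_error(bias_correct(list(mk(1, 50), mk(2, -50))), "zero-conflict")
})

test_that("pooling recovers a shared bimodal threshold across conflicts", {
  set.seed(404)
  sigma <- 80
  mus <- c(-40, 0, 40)  # conflict-dependent PSE shifts
  trs <- lapply(mus, function(m) sim_trials(90, m, sigma, spread = 120))
  fits <- Map(function(tr, d) fit_cumulative_gaussian(tr, "bimodal", d),
              trs, c(-50, 0, 50))
  pooled <- pooled_bimodal_threshold(trs, fits, n_boot = 50, seed = 6)
  # 4x the sigma-only Fisher SE at the true parameters and placements
  z <- unlist(Map(function(tr, m) (tr$probe_offset - m) / sigma, trs, mus))
  w <- dnorm(z)^2 / (pnorm(z) * (1 - pnorm(z)))
  se_sigma <- sigma / sqrt(sum(w * z^2))
  expect_lt(abs(pooled$threshold - sigma), 4 * se_sigma)
  expect_equal(pooled$pse, 0)
  expect_equal(pooled$n_trials, 270L)

  # permuting condition labels leaves the pooled threshold unchanged
  perm <- c(3, 1, 2)
  pooled_p <- pooled_bimodal_threshold(trs[perm], fits[perm], n_boot = 0)
  expect_equal(pooled_p$threshold, pooled$threshold, tolerance = 1e-8)

  # pooling one condition reproduces that condition's threshold
  single <- pooled_bimodal_threshold(trs[2], fits[2], n_boot = 0)
  expect_equal(single$threshold, fits[[2]]$threshold, tolerance = 0.05)
})

test_that("fits recover the generative model's analytic PSE and noise", {
  # trial data straight from the observer model (no adaptive placement)
  params <- observer_params(5, 9, "optimal")
  comb <- avbisect:::effective_combination(params)
  delta <- 4.5
  # raw-frame analytic PSE: weighted cue offsets null out
  mu_true <- (2 * comb$w_A - 1) * delta
  set.seed(77)
  n <- 800
  x <- rnorm(n, mu_true, 8)
  resp <- vapply(x, function(xx) {
    simulate_trial(trial_spec("space", "bimodal", delta, xx), params)
  }, integer(1L))
  f <- fit_cumulative_gaussian(data.frame(probe_offset = x, response = resp))
  se <- fisher_se(x, mu_true, comb$sigma_eff)
  expect_lt(abs(f$pse - mu_true), 4 * se$pse_se)
  expect_lt(abs(f$threshold - comb$sigma_eff), 4 * se$threshold_se)
})
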