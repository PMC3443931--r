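test_that("the predicted bimodal threshold follows the harmonic form", {
  expect_equal(predict_bimodal_sigma(1, 1) * sqrt(2), 1)
  expect_equal(predict_bimodal_sigma(3, 4), 2.4)
  expect_equal(predict_bimodal_sigma(1, 1e6), 1, tolerance = 1e-9)
  expect_error(predict_bimodal_sigma(-1, 1))

  # symmetry and scale equivariance
  set.seed(8)
  for (i in 1:50) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50); k <- runif(1, 0.1, 10)
    expect_equal(predict_bimodal_sigma(a, b), predict_bimodal_sigma(b, a))
    expect_equal(predict_bimodal_sigma(k * a, k * b),
                 k * predict_bimodal_sigma(a, b), tolerance = 1e-12)
    expect_lte(predict_bimodal_sigma(a, b), min(a, b))
  }
})

test_that("threshold-derived weights are variance ratios summing to one", {
  w <- weights_from_thresholds(1, 2)
  expect_equal(w$w_V, 0.8)
  expect_equal(w$w_A, 0.2)
  expect_equal(weights_from_thresholds(1, 1)$w_V, 0.5)
  expect_error(weights_from_thresholds(0, 1))
})

test_that("predicted PSEs follow the symmetric conflict line", {
  expect_equal(predict_pse(weights_from_slope(1), 4.5), 4.5)    # visual line
  expect_equal(predict_pse(weights_from_slope(0), 50), 0)       # balanced
  expect_equal(predict_pse(weights_from_slope(-1), 50), -50)    # auditory line
  w <- weights_from_thresholds(3, 4)
  d <- c(-9, -4.5, 0, 4.5, 9)
  expect_equal(predict_pse(w, d), (1 - 2 * w$w_A) * d)
  expect_equal(predict_pse(w, -d), -predict_pse(w, d))  # odd in conflict
})

test_that("slope estimation matches the OLS closed form and edge cases", {
  pts <- data.frame(conflict = c(-50, 0, 50),
                    pse_corrected = 0.6 * c(-50, 0, 50))
  expect_equal(slope_from_pses(pts)$slope, 0.6)
  pts2 <- data.frame(conflict = c(-50, 0, 50), pse_corrected = c(50, 0, -50))
  expect_equal(slope_from_pses(pts2)$slope, -1)
  expect_error(slope_from_pses(data.frame(conflict = c(1, 1),
                                          pse_corrected = c(0, 1))),
               "distinct")
  # closed-form cross-check against lm()
  set.seed(19)
  pts3 <- data.frame(conflict = c(-9, -4.5, 0, 4.5, 9),
                     pse_corrected = rnorm(5))
  sl <- slope_from_pses(pts3)
  lf <- lm(pse_corrected ~ conflict, pts3)
  expect_equal(sl$slope, unname(coef(lf)[2]))
  expect_equal(sl$slope_se, unname(sqrt(diag(vcov(lf)))[2]))
})

test_that("the OLS slope is unbiased over a simulated cohort", {
  set.seed(55)
  slopes <- replicate(200, {
    pts <- data.frame(conflict = c(-50, 0, 50),
                      pse_corrected = 0.2 * c(-50, 0, 50) + rnorm(3, 0, 5))
    slope_from_pses(pts)$slope
  })
  expect_gt(mean(slopes), 0.17)
  expect_lt(mean(slopes), 0.23)
})

test_that("slope-derived weights follow the conflict-slope relation", {
  expect_equal(weights_from_slope(1)$w_A, 0)
  expect_equal(weights_from_slope(-1)$w_A, 1)
  expect_equal(weights_from_slope(0)$w_A, 0.5)
  # out-of-range slopes give out-of-range weights, preserved and flagged
  w <- weights_from_slope(-1.4)
  expect_equal(w$w_A, 1.2)
  expect_false(w$in_range)
  expect_true(weights_from_slope(0.3)$in_range)
})

test_that("noiseless round trip recovers the auditory weight exactly", {
  design_deltas <- c(-9, -4.5, 0, 4.5, 9)
  for (w_A_true in c(0, 0.17, 0.5, 0.83, 1)) {
    w <- weights_from_slope(1 - 2 * w_A_true)
    pts <- data.frame(conflict = design_deltas,
                      pse_corrected = predict_pse(w, design_deltas))
    w_back <- weights_from_slope(slope_from_pses(pts))
    expect_equal(w_back$w_A, w_A_true, tolerance = 1e-12)
  }
})

test_that("the symmetric frame sends dominance to slope +/-1 in both domains", {
  # analytic raw-frame PSEs (what the fits estimate), then symmetrization
  raw_pse <- function(domain, rule, delta) {
    p <- observer_params(5, 5, rule)
    comb <- avbisect:::effective_combination(p)
    if (domain == "time") -2 * comb$w_A * delta else (2 * comb$w_A - 1) * delta
  }
  for (domain in c("time", "space")) {
    deltas <- if (domain == "time") c(-50, 0, 50) else c(-9, -4.5, 0, 4.5, 9)
    for (rule in c("visual_capture", "auditory_capture", "optimal")) {
      corr <- data.frame(conflict = deltas,
                         pse_corrected = raw_pse(domain, rule, deltas),
                         pse_se = 1)
      sym <- conflict_pse(corr, domain)
      sl <- slope_from_pses(sym)$slope
      expected <- switch(rule, visual_capture = 1, auditory_capture = -1,
                         optimal = 0)  # equal sigmas: balanced weights
      expect_equal(sl, expected, tolerance = 1e-10)
    }
  }
})

test_that("fitted sessions recover the integrator's weights end to end", {
  # optimal observers: slope-derived w_A close to the generating Eq-3 value
  n_rep <- 20
  ok <- logical(n_rep)
  design <- bisection_design("space")
  for (i in seq_len(n_rep)) {
    params <- observer_params(5, 10, "optimal", seed = 5000 + i)
    sess <- simulate_session(params, design, run_training = FALSE)
    fits <- fit_session(sess, n_boot = 0)
    bi <- fits$fits[grep("^bimodal@", names(fits$fits))]
    w_slope <- weights_from_slope(slope_from_pses(conflict_pse(bi, "space")))
    ok[i] <- abs(w_slope$w_A - weights_from_thresholds(5, 10)$w_A) < 0.12
  }
  expect_gte(mean(ok), 0.9)
})

test_that("visual-capture sessions fall right of the integration diagonal", {
  # with comparable unimodal noise, the slope-derived auditory weight
  # collapses toward 0 while the threshold-derived weight stays mid-range
  design <- bisection_design("space")
  diffs <- sapply(1:8, function(i) {
    params <- observer_params(5, 6, "visual_capture", seed = 7000 + i)
    sess <- simulate_session(params, design, run_training = FALSE)
    fits <- fit_session(sess, n_boot = 0)
    bi <- fits$fits[grep("^bimodal@", names(fits$fits))]
    w_slope <- weights_from_slope(slope_from_pses(conflict_pse(bi, "space")))
    w_thr <- weights_from_thresholds(5, 6)  # generating thresholds
    w_slope$w_A - w_thr$w_A
  })
  expect_lt(median(diffs), -0.2)
})
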