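test_that("observer parameters are validated", {
  expect_error(observer_params(-1, 1), "sigma_V")
  expect_error(observer_params(1, 1, lapse = 0.2), "lapse")
  expect_error(observer_params(1, 1, rule = "fixed_weights"), "w_A_fixed")
  p <- observer_params(1, 2, "fixed_weights", w_A_fixed = 0.3, lapse = 0.05)
  expect_s3_class(p, "observer_params")
})

test_that("response probability matches the generative model's closed form", {
  # saturation far from the bisection point
  p <- observer_params(10, 10, "optimal")
  expect_equal(response_probability(trial_spec("time", "visual", 0, 1e6), p), 1)
  expect_equal(response_probability(trial_spec("time", "visual", 0, -1e6), p), 0)

  # auditory capture: indifferent exactly at the auditory midpoint
  pa <- observer_params(100, 50, "auditory_capture")
  expect_equal(response_probability(
    trial_spec("time", "bimodal", 50, -100), pa), 0.5)

  # optimal combination of equal cues: sigma_eff = 1/sqrt(2)
  po <- observer_params(1, 1, "optimal")
  expect_equal(response_probability(
    trial_spec("space", "bimodal", 0, sqrt(0.5)), po),
    pnorm(1), tolerance = 1e-12)

  # lapse compresses the range symmetrically
  pl <- observer_params(1, 1, "optimal", lapse = 0.1)
  expect_equal(response_probability(trial_spec("space", "visual", 0, 1e6), pl),
               0.95)
  expect_equal(response_probability(trial_spec("space", "visual", 0, 0), pl),
               0.5)
})

test_that("capture and fixed-weight rules use the stated effective noise", {
  p <- observer_params(3, 4, "fixed_weights", w_A_fixed = 0.25)
  comb <- avbisect:::effective_combination(p)
  expect_equal(comb$sigma_eff, sqrt(0.75^2 * 9 + 0.25^2 * 16))
  expect_equal(avbisect:::effective_combination(
    observer_params(3, 4, "visual_capture"))$sigma_eff, 3)
  expect_equal(avbisect:::effective_combination(
    observer_params(3, 4, "auditory_capture"))$sigma_eff, 4)
  # optimal rule: weights are the variance-ratio weights, noise the
  # harmonic combination
  co <- avbisect:::effective_combination(observer_params(3, 4, "optimal"))
  expect_equal(co$w_V, 16 / 25)
  expect_equal(co$sigma_eff, 2.4)
})

test_that("simulated responses converge to the model probability", {
  set.seed(41)
  cases <- list(
    list(spec = trial_spec("time", "bimodal", 50, 30),
         params = observer_params(120, 80, "optimal")),
    list(spec = trial_spec("space", "bimodal", -9, 4),
         params = observer_params(5, 9, "visual_capture")),
    list(spec = trial_spec("space", "bimodal", 4.5, -2),
         params = observer_params(5, 9, "fixed_weights", w_A_fixed = 0.4,
                                  lapse = 0.05)),
    list(spec = trial_spec("time", "auditory", 0, -40),
         params = observer_params(100, 60, "auditory_capture"))
  )
  n <- 1e5
  for (cs in cases) {
    p <- response_probability(cs$spec, cs$params)
    hits <- sum(vapply(seq_len(n), function(i) simulate_trial(cs$spec, cs$params),
                       integer(1L)))
    # within 3 binomial SDs
    expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("training screen reproduces the 7-of-10 inclusion rule", {
  set.seed(7)
  sharp <- observer_params(1e-6, 1e-6, "optimal")
  expect_true(simulate_training_screen(sharp, "time")$passed)

  # pass_threshold 0 always passes
  noisy <- observer_params(50, 50, "optimal")
  expect_true(simulate_training_screen(noisy, "time", pass_threshold = 0)$passed)

  # a pure guesser (easy offset 0 -> p = 0.5 per trial) passes with the
  # exact binomial tail probability sum(C(10,k)/2^10, k=7..10) = 0.171875
  reps <- 2e4
  passed <- vapply(seq_len(reps), function(i) {
    simulate_training_screen(noisy, "time", easy_offset = 0)$passed
  }, logical(1L))
  p_exact <- sum(choose(10, 7:10)) / 2^10
  expect_equal(p_exact, 0.171875)
  expect_lt(abs(mean(passed) - p_exact),
            4 * sqrt(p_exact * (1 - p_exact) / reps))
})

test_that("simulated sessions satisfy the design invariants and are reproducible", {
  p <- observer_params(120, 80, "optimal", seed = 99)
  s1 <- simulate_session(p, bisection_design("time"))
  expect_equal(nrow(s1$trials), 150)
  expect_equal(as.vector(table(s1$trials$condition)[c("auditory", "bimodal", "visual")]),
               c(30, 90, 30))
  counts <- table(s1$trials$conflict[s1$trials$condition == "bimodal"])
  expect_true(all(counts == 30))

  s2 <- simulate_session(p, bisection_design("time"))
  expect_identical(s1$trials, s2$trials)  # same seed, same table

  ps <- observer_params(5, 10, "optimal", seed = 3)
  ss <- simulate_session(ps, bisection_design("space"))
  expect_equal(nrow(ss$trials), 210)
  expect_equal(length(unique(paste(ss$trials$condition, ss$trials$conflict))), 7)

  expect_error(bisection_design("time", trials_per_condition = 0),
               "positive integer")
})

test_that("a session leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_session(observer_params(5, 10, "optimal", seed = 8),
                             bisection_design("space")))
  expect_identical(.Random.seed, before)
})
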