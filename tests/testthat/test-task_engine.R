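# Staircase engine: hand-traced oracles, bisection bracket property,
# round-trip scoring, log validation.

test_that("hyperbolic_value matches the closed form and rejects bad input", {
  expect_equal(hyperbolic_value(100, 0, 365), 100)
  expect_equal(hyperbolic_value(100, 1, 1), 50)
  expect_equal(hyperbolic_value(100, 0.05, 30), 40)
  expect_equal(hyperbolic_value(100, 0.05, 0), 100)
  expect_error(hyperbolic_value(-1, 0.1, 10), "non-negative")
  expect_error(hyperbolic_value(100, -0.1, 10), "non-negative")
})

test_that("simulate_choice thresholds, ties, and the high-temperature limit", {
  cfg <- task_config()
  expect_true(simulate_choice(dd_agent(0.05), 50, 30, cfg))
  expect_false(simulate_choice(dd_agent(0), 99, 1, cfg))
  # tie at exact indifference: value = 40 at k=.05, delay 30
  expect_false(simulate_choice(dd_agent(0.05), 40, 30, cfg))
  cfg_imm <- task_config(tie_rule = "prefer_immediate")
  expect_true(simulate_choice(dd_agent(0.05), 40, 30, cfg_imm))
  expect_error(simulate_choice(dd_agent(0), 100, 1, cfg), "strictly between")
  # temperature -> Inf: choice probability -> 1/2 regardless of the offer
  set.seed(11)
  hot <- dd_agent(0.05, noise_temperature = 1e9)
  draws <- replicate(2000, simulate_choice(hot, 5, 365, cfg))
  expect_gt(mean(draws), 0.45)
  expect_lt(mean(draws), 0.55)
})

test_that("six-trial staircase reproduces the hand-traced offer sequences", {
  # always-delayed responder (k = 0): offers climb, IP = 99.21875
  r <- run_adjusting_staircase(dd_agent(0), delay = 30)
  expect_equal(r$trials$immediate_amount,
               c(50, 75, 87.5, 93.75, 96.875, 98.4375))
  expect_identical(r$indifference_point, 99.21875)
  # always-immediate responder (huge k): offers fall, IP = 0.78125
  r <- run_adjusting_staircase(dd_agent(1e12), delay = 30)
  expect_equal(r$trials$immediate_amount,
               c(50, 25, 12.5, 6.25, 3.125, 1.5625))
  expect_identical(r$indifference_point, 0.78125)
  # threshold responder around value 40 (k = .05, 30 days)
  r <- run_adjusting_staircase(dd_agent(0.05), delay = 30)
  expect_equal(r$trials$immediate_amount,
               c(50, 25, 37.5, 43.75, 40.625, 39.0625))
  expect_identical(r$indifference_point, 39.84375)
})

test_that("full task: flat profile at k = 0, monotone profile for k > 0,
           deterministic under a fixed seed with noise", {
  flat <- run_full_task(dd_agent(0))$profile
  expect_equal(flat$points, rep(99.21875, 5))
  mono <- run_full_task(dd_agent(0.05))$profile
  expect_true(all(diff(mono$points) <= 0))
  set.seed(42)
  a <- run_full_task(dd_agent(0.03, noise_temperature = 3))$profile
  set.seed(42)
  b <- run_full_task(dd_agent(0.03, noise_temperature = 3))$profile
  expect_identical(a$points, b$points)
})

test_that("staircase brackets the true value within the final step size", {
  set.seed(7)
  cfg <- task_config()
  final_step <- cfg$start_fraction * cfg$llr_amount * 2^(-cfg$trials_per_delay)
  ks <- exp(runif(500, log(1e-4), log(10)))
  delays <- sample(cfg$delays, 500, replace = TRUE)
  for (i in seq_len(500)) {
    v <- hyperbolic_value(cfg$llr_amount, ks[i], delays[i])
    ip <- run_adjusting_staircase(dd_agent(ks[i]), delays[i], cfg)$indifference_point
    expect_lte(abs(ip - v), final_step)
    expect_gte(ip, 0)
    expect_lte(ip, cfg$llr_amount)
  }
})

test_that("score_choice_log round-trips and flags corrupted or short logs", {
  cfg <- task_config()
  set.seed(5)
  run <- run_full_task(dd_agent(0.02, noise_temperature = 4), cfg, "kid7")
  rescored <- score_choice_log(run$trials, cfg)
  expect_identical(rescored$points, run$profile$points)
  expect_identical(rescored$participant_id, "kid7")

  bad <- run$trials
  i <- which(bad$delay_days == 30 & bad$trial_index == 3)
  bad$immediate_amount[i] <- bad$immediate_amount[i] + 1
  err <- expect_error(score_choice_log(bad, cfg), class = "dd_log_error")
  expect_equal(err$delay, 30)
  expect_equal(err$trial, 3)

  short <- run$trials[-i, ]
  expect_error(score_choice_log(short, cfg), "expected 6 trials",
               class = "dd_log_error")
  two <- rbind(run$trials,
               transform(run$trials, participant_id = "other"))
  expect_error(score_choice_log(two, cfg), "more than one participant",
               class = "dd_log_error")
})

test_that("task_config validates its invariants", {
  expect_error(task_config(delays = c(7, 1)), "strictly increasing")
  expect_error(task_config(start_fraction = 1))
  expect_error(task_config(trials_per_delay = 0))
  expect_error(dd_agent(-1))
  expect_error(dd_profile("x", five_delays, c(1, 2, 3, 4, 101), 100),
               "\\[0, llr_amount\\]")
})
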