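test_that("the 1-up-1-down update rule steps, clamps and counts reversals", {
  cfg <- staircase_config(start_value = 0.5, step = 0.05)
  s <- staircase_new(cfg)
  s <- step_staircase(s, "comparison_more_intense")
  expect_equal(s$current_value, 0.45)

  # clamp at the lower bound
  s2 <- staircase_new(staircase_config(start_value = 0.02, step = 0.05))
  s2 <- step_staircase(s2, "comparison_more_intense")
  expect_equal(s2$current_value, 0)

  # down, down, up -> exactly one reversal, at the turn's presented value
  s3 <- staircase_new(cfg)
  s3 <- step_staircase(s3, "comparison_more_intense")   # 0.50 -> 0.45
  s3 <- step_staircase(s3, "comparison_more_intense")   # 0.45 -> 0.40
  s3 <- step_staircase(s3, "vibration_more_intense")    # reversal at 0.40
  expect_equal(length(s3$reversal_values), 1L)
  expect_equal(s3$reversal_values, 0.40)
})

test_that("termination rules fire with the right precedence and reasons", {
  cfg <- staircase_config()
  # reversals rule: alternate responses until 8 reversals
  s <- staircase_new(cfg)
  resp <- c("comparison_more_intense", "vibration_more_intense")
  i <- 0
  while (!s$finished) {
    i <- i + 1
    s <- step_staircase(s, resp[(i %% 2) + 1])
  }
  expect_equal(s$termination_reason, "reversals")
  expect_equal(length(s$reversal_values), 8L)
  expect_lt(length(s$presented), 50)

  # trials rule: monotone run never reverses, hits the floor then sits there
  s <- staircase_new(cfg)
  while (!s$finished) s <- step_staircase(s, "comparison_more_intense")
  expect_equal(s$termination_reason, "trials")
  expect_equal(length(s$presented), 50L)

  # plateau rule: ceiling reached and held for the last ten trials
  s <- staircase_new(staircase_config(start_value = 0.9))
  while (!s$finished) s <- step_staircase(s, "vibration_more_intense")
  expect_equal(s$termination_reason, "plateau")
  n <- length(s$presented)
  expect_true(all(s$presented[(n - 9):n] == 1))

  expect_error(step_staircase(s, "vibration_more_intense"), "finished")
})

test_that("PSE is the mean of the final six reversals", {
  s <- staircase_new(staircase_config())
  s$reversal_values <- c(0.40, 0.50, 0.42, 0.52, 0.44, 0.50, 0.44, 0.50)
  est <- pse_from_reversals(s)
  expect_equal(est$pse, 0.47)
  expect_false(est$degraded)

  s$reversal_values <- rep(0.3, 6)
  expect_equal(pse_from_reversals(s)$pse, 0.3)

  # fewer reversals than requested: degraded average of what exists
  s$reversal_values <- c(0.4, 0.5)
  est <- pse_from_reversals(s)
  expect_equal(est$pse, 0.45)
  expect_true(est$degraded)

  s$reversal_values <- numeric(0)
  expect_error(pse_from_reversals(s), "no reversals")
})

test_that("a deterministic threshold observer is recovered within one step", {
  obs <- simulated_observer(pse = 0.6, slope = 0)
  r <- run_simulated_staircase(obs, staircase_config(start_value = 0.2),
                               seed = 4)
  expect_lt(abs(r$pse_estimate - 0.6), 0.05 + 1e-12)
})

test_that("an out-of-range PSE forces plateau termination", {
  obs <- simulated_observer(pse = 1.5, slope = 0)
  r <- run_simulated_staircase(obs, staircase_config(start_value = 0.5),
                               seed = 4)
  expect_equal(r$termination_reason, "plateau")
  expect_true(r$degraded)
})

test_that("staircase runs stay in bounds, terminate, and are seed-stable", {
  obs <- simulated_observer(pse = 0.5, slope = 0.1, lapse_rate = 0.05)
  for (seed in 1:20) {
    r <- run_simulated_staircase(obs, staircase_config(), seed = seed)
    expect_true(all(r$state$presented >= 0 & r$state$presented <= 1))
    expect_lte(r$n_trials, 50)
  }
  a <- run_simulated_staircase(obs, staircase_config(), seed = 123)
  b <- run_simulated_staircase(obs, staircase_config(), seed = 123)
  expect_identical(a$state$presented, b$state$presented)
})
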