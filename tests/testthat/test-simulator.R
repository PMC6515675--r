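test_that("fixed-design trials always run to the maximum sample size", {
  d1 <- builtin_designs()$design1
  scn <- builtin_scenarios()$no_difference
  tr <- simulate_trial(d1, scn, seed = 7)
  expect_identical(tr$stop_reason, "completed")
  expect_identical(tr$n_randomised, 1006L)
  expect_identical(simulate_trial(d1, scn, seed = 7), tr) # deterministic
  # duration = accrual end + follow-up: ~183 weeks of Poisson accrual at
  # 5.5/week (sd ~6) plus the 30-day window
  expect_lt(abs(tr$duration_weeks - (1006 / 5.5 + 30 / 7)), 5 * sqrt(1006) / 5.5)
})

test_that("a design with unreachable boundaries reproduces the fixed design", {
  scn <- builtin_scenarios()$target
  d1 <- builtin_designs()$design1
  d_never <- design_spec("never", interims = data.frame(n = c(335, 670),
                                                        success = 1, futility = 0))
  for (s in c(11, 12, 13)) {
    expect_identical(simulate_trial(d_never, scn, seed = s, n_draws = 200),
                     simulate_trial(d1, scn, seed = s))
  }
})

test_that("operating characteristics partition the replicates and reproduce", {
  d2 <- builtin_designs()$design2
  scn <- builtin_scenarios()$harmful
  oc <- operating_characteristics(d2, scn, n_sims = 40, seed = 21, n_draws = 400)
  trials <- tidy(oc)
  expect_identical(nrow(trials), 40L)
  p_complete <- mean(trials$stop_reason == "completed")
  expect_equal(oc$prop_stop_success + oc$prop_stop_futility + p_complete, 1)
  expect_true(all(!trials$successful[trials$stop_reason == "futility_stop"]))
  expect_lte(oc$mean_n, d2$n_max)
  # bit-identical on re-run with the same master seed
  oc_again <- operating_characteristics(d2, scn, n_sims = 40, seed = 21, n_draws = 400)
  expect_identical(tibble::as_tibble(oc), tibble::as_tibble(oc_again))
  # harmful truth should stop early for futility most of the time
  expect_gt(oc$prop_stop_futility, 0.7)
})

test_that("simulated streams recover the scenario parameters", {
  scn <- scenario_spec(0.45, 0.45, dropout = 0.03)
  stream <- generate_stream(scn, 10000, seed = 3)
  dead <- mean(stream$outcome[!is.na(stream$outcome)])
  expect_lt(abs(dead - 0.45), 3 * sqrt(0.45 * 0.55 / 10000))
  expect_lt(abs(mean(is.na(stream$outcome)) - 0.03), 3 * sqrt(0.03 * 0.97 / 10000))
  expect_lt(abs(mean(stream$arm == "control") - 0.5), 3 * sqrt(0.25 / 10000))
  # mean inter-arrival 1/5.5 weeks
  expect_equal(mean(diff(stream$recruit_week)), 1 / 5.5, tolerance = 0.05)
  expect_identical(generate_stream(scn, 10000, seed = 3), stream)
})

test_that("threshold calibration flags candidates and uses common random numbers", {
  template <- design_spec("one look", interims = data.frame(n = 503, success = 0.99,
                                                            futility = 0.05))
  scns <- list(scenario_spec(0.45, 0.45, label = "null"),
               scenario_spec(0.45, 0.36, label = "target"))
  grid <- calibrate_thresholds(template,
                               s_grid = list(1), f_grid = list(0, 0.3),
                               scenarios = scns, n_sims = 25, seed = 5,
                               n_draws = 300, type1_cap = 0.1, power_floor = 0.5)
  expect_identical(nrow(grid), 4L) # 2 candidates x 2 scenarios
  # unreachable boundaries equal the fixed design's OCs on shared seeds
  oc_fixed <- operating_characteristics(builtin_designs()$design1, scns[[2]],
                                        n_sims = 25, seed = 5)
  inert <- grid[grid$scenario == "target" &
                  vapply(grid$futility_thresholds, function(f) all(f == 0), TRUE), ]
  expect_equal(inert$prop_successful, oc_fixed$prop_successful)
  expect_equal(inert$mean_n, oc_fixed$mean_n)
  # with common random numbers, shrinking F can only reduce futility stops
  null_rows <- grid[grid$scenario == "null", ]
  f_of <- vapply(null_rows$futility_thresholds, `[[`, 0, 1)
  expect_lte(null_rows$prop_stop_futility[f_of == 0],
             null_rows$prop_stop_futility[f_of == 0.3])
  expect_true(all(c("type1", "power", "flagged") %in% names(grid)))
})
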