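test_that("zero unresolved patients gives the final-success indicator", {
  snap_no <- interim_snapshot(100, 100, 100, 100, 45, 40)
  res <- predictive_prob_current(snap_no)
  expect_true(res$probability %in% c(0, 1))
  expect_equal(res$probability,
               as.numeric(final_success(45, 100, 40, 100)))
  expect_identical(res$method, "degenerate")

  snap_win <- interim_snapshot(100, 100, 100, 100, 60, 20)
  expect_equal(predictive_prob_current(snap_win)$probability, 1)
  # at n_max with everyone complete, P_max is the same indicator
  expect_equal(predictive_prob_max(snap_win, n_max = 200)$probability, 1)
  expect_equal(predictive_prob_max(snap_no, n_max = 200)$probability, 0)
})

test_that("enumeration matches the per-sequence brute-force oracle", {
  cases <- list(
    # randC, randT, compC, compT, dC, dT, threshold
    list(9, 9, 8, 8, 3, 1, 0.60),
    list(9, 9, 8, 8, 3, 1, 0.80),
    list(12, 11, 9, 9, 5, 2, 0.70),
    # 0.55 rather than 0.50: symmetric completions can land exactly on 0.5,
    # where the oracle's quadrature and the closed form may break the
    # measure-zero tie differently
    list(10, 10, 7, 8, 2, 4, 0.55)
  )
  for (cs in cases) {
    snap <- interim_snapshot(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]], cs[[6]])
    pkg <- predictive_prob_current(snap, final_threshold = cs[[7]])
    expect_identical(pkg$method, "enumeration")
    oracle <- oracle_predictive(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]], cs[[6]],
                                threshold = cs[[7]])
    expect_equal(pkg$probability, oracle, tolerance = 1e-10)
  }
})

test_that("tiny-trial P_max equals brute-force enumeration over future patients", {
  # 4 complete of 4 randomised, n_max 8: two future patients per arm
  snap <- interim_snapshot(2, 2, 2, 2, 1, 1)
  pkg <- predictive_prob_max(snap, n_max = 8, dropout = 0, final_threshold = 0.6)
  expect_identical(pkg$method, "enumeration")
  oracle <- oracle_predictive(2, 2, 2, 2, 1, 1, threshold = 0.6,
                              future_c = 2, future_t = 2)
  expect_equal(pkg$probability, oracle, tolerance = 1e-10)
})

test_that("Monte Carlo converges to the enumeration value", {
  snap <- interim_snapshot(12, 11, 9, 9, 5, 2)
  exact <- predictive_prob_current(snap, final_threshold = 0.7)$probability
  for (s in c(2, 5)) {
    mc <- predictive_prob_current(snap, final_threshold = 0.7,
                                  n_draws = 20000, seed = s, enumerate_limit = 0)
    expect_identical(mc$method, "monte_carlo")
    expect_lt(abs(mc$probability - exact), 3 * sqrt(exact * (1 - exact) / 20000) + 1e-9)
  }
})

test_that("P_max orders stochastically with the interim death counts", {
  # enumeration on a grid of small snapshots: more control deaths (or fewer
  # treatment deaths) can only help the treatment
  pm <- function(dc, dt) {
    predictive_prob_max(interim_snapshot(8, 8, 6, 6, dc, dt),
                        n_max = 20, dropout = 0, final_threshold = 0.6)$probability
  }
  for (dt in 0:3) {
    vals <- vapply(0:5, pm, 0, dt = dt)
    expect_true(all(diff(vals) >= -1e-12))
  }
  for (dc in 2:5) {
    vals <- vapply(0:4, function(dt) pm(dc, dt), 0)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("Monte-Carlo P_max is stable across seeds", {
  snap <- interim_snapshot(129, 121, 118, 113, 49, 44)
  n_draws <- 5000
  vals <- vapply(1:4, function(s) {
    predictive_prob_max(snap, n_max = 1006, seed = s, n_draws = n_draws)$probability
  }, 0)
  p <- mean(vals)
  expect_lt(max(vals) - min(vals), 2 * 4 * sqrt(p * (1 - p) / n_draws))
})

test_that("the Monte-Carlo path demands a seed and valid inputs", {
  snap <- interim_snapshot(60, 60, 30, 30, 10, 10)
  expect_error(predictive_prob_current(snap), "seed")
  expect_error(predictive_prob_max(snap, n_max = 100), "n_max")
  expect_silent(predictive_prob_max(snap, n_max = 120, seed = 1, n_draws = 100))
})
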