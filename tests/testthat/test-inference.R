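test_that("conjugate update adds deaths to alpha and survivors to beta", {
  expect_equal(unclass(beta_posterior(0, 0)), list(alpha = 1, beta = 1))
  p <- beta_posterior(49, 118)
  expect_equal(c(p$alpha, p$beta), c(50, 70))
  p2 <- beta_posterior(3, 10, prior_alpha = 2, prior_beta = 5)
  expect_equal(c(p2$alpha, p2$beta), c(5, 12))
  expect_error(beta_posterior(5, 3), "exceed")
  expect_error(beta_posterior(1, 2, prior_alpha = 0), "positive")
})

test_that("probability of superiority: exact value, symmetry, method agreement", {
  # hand-derived closed form: Beta(1,2) treatment vs Beta(2,1) control
  expect_equal(prob_superiority(c(1, 2), c(2, 1))$prob_superior, 5 / 6,
               tolerance = 1e-12)
  same <- beta_posterior(50, 120)
  expect_equal(prob_superiority(same, same)$prob_superior, 0.5, tolerance = 1e-10)

  # closed form and quadrature agree on a grid of count-based posteriors
  set.seed(41)
  for (i in 1:12) {
    n1 <- sample(5:400, 1); n2 <- sample(5:400, 1)
    d1 <- rbinom(1, n1, runif(1, 0.1, 0.6)); d2 <- rbinom(1, n2, runif(1, 0.1, 0.6))
    t_post <- beta_posterior(d1, n1)
    c_post <- beta_posterior(d2, n2)
    cf <- prob_superiority(t_post, c_post, method = "closed_form")$prob_superior
    qd <- prob_superiority(t_post, c_post, method = "quadrature")$prob_superior
    expect_equal(cf, qd, tolerance = 1e-8)
    # complement identity: the event is continuous
    expect_equal(cf + prob_superiority(c_post, t_post)$prob_superior, 1,
                 tolerance = 1e-8)
  }

  # Monte-Carlo path agrees within 3 standard errors
  t_post <- beta_posterior(93, 239); c_post <- beta_posterior(96, 230)
  exact <- prob_superiority(t_post, c_post)$prob_superior
  mc <- prob_superiority(t_post, c_post, method = "monte_carlo",
                         n_draws = 1e6, seed = 7)$prob_superior
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 1e6))
})

test_that("probability of superiority is monotone in the death counts", {
  base <- function(dt, dc) {
    prob_superiority(beta_posterior(dt, 100), beta_posterior(dc, 100))$prob_superior
  }
  for (d in c(10, 40, 70)) {
    expect_gt(base(d, d + 1), base(d, d))     # more control deaths
    expect_lt(base(d + 1, d), base(d, d))     # more treatment deaths
  }
})

test_that("final success rule is strict at the threshold", {
  expect_false(final_success(163, 397, 166, 398))
  expect_true(final_success(100, 100, 0, 100))
  expect_false(final_success(50, 100, 50, 100, threshold = 0.51))
  # strict inequality: a threshold equal to the posterior probability fails
  p <- attr(final_success(100, 200, 80, 200), "prob_superior")
  expect_false(final_success(100, 200, 80, 200, threshold = p))
  expect_true(final_success(100, 200, 80, 200, threshold = p - 1e-9))
})

test_that("relative risk reproduces the published intervals at 2 dp", {
  rr <- relative_risk(166, 398, 163, 397)
  expect_equal(round(rr$rr, 2), 1.02)
  expect_equal(round(rr$ci_low, 2), 0.86)
  expect_equal(round(rr$ci_high, 2), 1.20)
  expect_equal(round(relative_risk(134, 331, 138, 339)$rr, 2), 0.99)
  expect_equal(relative_risk(50, 100, 50, 100)$rr, 1)

  wide <- relative_risk(166, 398, 163, 397, level = 0.99)
  expect_lt(wide$ci_low, rr$ci_low)
  expect_gt(wide$ci_high, rr$ci_high)
  expect_true(rr$ci_low <= rr$rr && rr$rr <= rr$ci_high)
  expect_error(relative_risk(0, 100, 10, 100), "zero cell")
})

test_that("continuity-corrected sample size reproduces the planned 503 per arm", {
  ss <- sample_size_two_proportions(0.45, 0.09, alpha = 0.05, power = 0.80,
                                    dropout = 0.03)
  expect_identical(ss$n_per_arm, 503L)
  expect_identical(ss$n_total, 1006L)
  # hand evaluation without dropout: uncorrected ~465.8, corrected ~487.8
  ss0 <- sample_size_two_proportions(0.45, 0.09)
  expect_identical(ss0$n_per_arm, 488L)
  expect_equal(ss0$n_uncorrected, 465.8, tolerance = 1e-3)
  expect_equal(ss0$n_corrected, 487.8, tolerance = 1e-3)
  expect_lt(ss0$n_per_arm, ss$n_per_arm)

  # monotone in effect size and power
  expect_gt(sample_size_two_proportions(0.45, 0.06)$n_per_arm,
            sample_size_two_proportions(0.45, 0.09)$n_per_arm)
  expect_gt(sample_size_two_proportions(0.45, 0.09, power = 0.9)$n_per_arm,
            sample_size_two_proportions(0.45, 0.09, power = 0.8)$n_per_arm)
  expect_error(sample_size_two_proportions(0.45, 0.45), "absolute_reduction")
})
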