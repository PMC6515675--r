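test_that("constrained fixtures reproduce every pinned snapshot exactly", {
  for (id in c("design2", "design3", "design4", "design5")) {
    cnt <- oscar_counts(id)
    fx <- oscar_fixture(id, seed = 8)
    chk <- verify_fixture(fx, cnt$constraints, cnt$final)
    expect_true(all(chk$match), label = sprintf("%s fixture matches", id))
    # independent loop-based recount at each trigger
    for (cc in cnt$constraints) {
      rc <- recount_snapshot(fx, cc$at_total)
      expect_equal(unname(rc$control),
                   unname(c(cc$randomised[["control"]], cc$complete[["control"]],
                            cc$deaths[["control"]])))
      expect_equal(unname(rc$treatment),
                   unname(c(cc$randomised[["treatment"]], cc$complete[["treatment"]],
                            cc$deaths[["treatment"]])))
    }
  }
})

test_that("fixtures respond to the seed but not in their constrained counts", {
  cnt <- oscar_counts("design5")
  fx_a <- oscar_fixture("design5", seed = 1)
  fx_b <- oscar_fixture("design5", seed = 2)
  expect_false(identical(fx_a$arm, fx_b$arm)) # shuffled arm order differs
  for (fx in list(fx_a, fx_b)) {
    expect_true(all(verify_fixture(fx, cnt$constraints, cnt$final)$match))
  }
})

test_that("an unconstrained fixture reduces to the scenario stream", {
  scn <- scenario_spec(0.45, 0.40)
  expect_identical(generate_fixture(scenario = scn, n_patients = 100, seed = 4),
                   generate_stream(scn, 100, seed = 4))
})

test_that("infeasible constraints fail with the violated inequality named", {
  scn <- scenario_spec(0.45, 0.40)
  c1 <- count_constraint(100, 50, 50, 40, 40, 10, 10)
  # complete count shrinks between triggers
  c2_bad <- count_constraint(200, 100, 100, 30, 80, 10, 20)
  expect_error(generate_fixture(list(c1, c2_bad), final = NULL, scenario = scn,
                                n_patients = 250, seed = 1),
               "complete decreases")
  # deaths exceed complete within the constraint itself
  expect_error(count_constraint(100, 50, 50, 40, 40, 45, 10), "deaths")
  # final analysed below the last trigger's complete count
  fin_bad <- count_constraint(220, 110, 110, 30, 35, 5, 5)
  expect_error(generate_fixture(list(c1), final = fin_bad, scenario = scn, seed = 1),
               "final analysed")
  # trigger spacing shorter than the follow-up window
  c_fast <- count_constraint(10, 5, 5, 2, 2, 1, 1)
  expect_error(generate_fixture(list(c_fast), final = NULL, scenario = scn,
                                n_patients = 30, seed = 1),
               "follow-up window")
})

test_that("fixtures with dropouts place them outside every analysis", {
  scn <- scenario_spec(0.45, 0.40)
  c1 <- count_constraint(100, 50, 50, 40, 40, 15, 12)
  fin <- count_constraint(160, 80, 80, 76, 77, 30, 25) # 4 + 3 dropouts
  fx <- generate_fixture(list(c1), final = fin, scenario = scn, seed = 6)
  expect_identical(nrow(fx), 160L)
  expect_identical(sum(is.na(fx$outcome) & fx$arm == "control"), 4L)
  expect_identical(sum(is.na(fx$outcome) & fx$arm == "treatment"), 3L)
  expect_true(all(verify_fixture(fx, list(c1), fin)$match))
})

test_that("fixtures survive the patient CSV round trip and drive re-execution", {
  dir <- withr::local_tempdir()
  fx <- oscar_fixture("design2", seed = 9)
  path <- file.path(dir, "fixture.csv")
  write_patients(fx, path)
  back <- read_patients(path)
  expect_identical(as.data.frame(back), as.data.frame(fx))
  rx <- reexecute(back, builtin_designs()$design2, n_draws = 1000, seed = 2)
  expect_identical(rx$stop_reason, "futility_stop")
  expect_identical(rx$n_randomised, 750L)
  expect_identical(rx$deaths_total, 310L)
})
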