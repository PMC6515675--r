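test_that("built-in designs carry the tabulated schedules and boundaries", {
  ds <- builtin_designs()
  expect_named(ds, paste0("design", 1:6))
  expect_identical(nrow(ds$design1$interims), 0L)

  d5 <- ds$design5
  expect_identical(d5$interims$n, c(503L, 755L))
  expect_equal(d5$interims$success, c(0.99, 0.98))
  expect_equal(d5$interims$futility, c(0.05, 0.10))

  d2 <- ds$design2
  expect_identical(d2$interims$n, c(250L, 500L, 750L))
  expect_true(is.na(d2$interims$success[1])) # no success stopping at interim 1
  expect_equal(d2$interims$futility, c(0.05, 0.10, 0.15))

  for (d in ds) {
    expect_s3_class(d, "design_spec")
    expect_identical(d$n_max, 1006L)
    expect_equal(d$final_threshold, 0.975)
    if (nrow(d$interims)) {
      expect_true(all(diff(d$interims$n) > 0))
      expect_true(all(d$interims$n < d$n_max))
    }
  }
})

test_that("design validation rejects broken schedules", {
  expect_error(design_spec("x", interims = data.frame(n = c(500, 400),
                                                      success = NA, futility = 0.1)),
               "increasing")
  expect_error(design_spec("x", n_max = 400,
                           interims = data.frame(n = 500, success = NA, futility = 0.1)),
               "below n_max")
  expect_error(design_spec("x", interims = data.frame(n = 500, success = 1.2,
                                                      futility = 0.1)),
               "thresholds")
})

test_that("interim decisions follow futility-first boundary logic", {
  ds <- builtin_designs()
  # second look of the two-look design on the observed counts: P_max ~ 0.013
  # sits far below F_2 = 0.1
  snap <- interim_snapshot(339, 331, 330, 322, 136, 129)
  dec <- interim_decision(snap, ds$design3, 2, n_draws = 4000, seed = 1)
  expect_identical(dec$action, "stop_futility")
  expect_lt(dec$p_max, 0.1)

  # first look of the three-look design: P_max ~ 0.24 >= F_1 = 0.05, and no
  # success boundary exists, so the trial continues with p_curr undefined
  snap1 <- interim_snapshot(129, 121, 118, 113, 49, 44)
  dec1 <- interim_decision(snap1, ds$design2, 1, n_draws = 4000, seed = 1)
  expect_identical(dec1$action, "continue")
  expect_true(is.na(dec1$p_curr))
  expect_gte(dec1$p_max, 0.05)

  # unreachable boundaries never stop under strict inequalities
  d_never <- design_spec("never", interims = data.frame(n = 250, success = 1,
                                                        futility = 0))
  dec2 <- interim_decision(snap1, d_never, 1, n_draws = 1000, seed = 1)
  expect_identical(dec2$action, "continue")

  expect_error(interim_decision(snap1, ds$design3, 1, seed = 1), "scheduled")
})

test_that("re-executing the two-look design reproduces its decision trail", {
  cnt <- oscar_counts("design3")
  fx <- oscar_fixture("design3", seed = 2)
  rx <- reexecute(fx, builtin_designs()$design3, n_draws = 4000, seed = 42)

  trail <- tidy(rx)
  expect_identical(trail$decision, c("continue", "stop_futility"))
  expect_equal(trail$p_superior[1], 0.8254, tolerance = 1e-3)
  expect_lt(trail$p_max[2], 0.1)

  fin <- glance(rx)
  expect_identical(fin$n_randomised, 670L)
  expect_identical(fin$deaths_total, 272L)
  expect_identical(c(fin$deaths_control, fin$analysed_control), c(138L, 339L))
  expect_identical(c(fin$deaths_treatment, fin$analysed_treatment), c(134L, 331L))
  expect_equal(fin$final_prob_superior, 0.5235, tolerance = 0.002)
  expect_equal(round(fin$rr, 2), 0.99)
  expect_false(fin$successful) # futility stop is unsuccessful regardless
  expect_identical(fin$savings_vs_n_max, 336L)
})

test_that("unreachable boundaries reduce to the fixed design's final analysis", {
  scn <- scenario_spec(0.45, 0.40, label = "toy")
  stream <- generate_stream(scn, 1006, seed = 99)
  d_fixed <- builtin_designs()$design1
  d_never <- design_spec("never", interims = data.frame(n = c(250, 500),
                                                        success = 1, futility = 0))
  rx_fixed <- reexecute(stream, d_fixed, seed = 1)
  rx_never <- reexecute(stream, d_never, n_draws = 500, seed = 1)
  expect_identical(length(rx_fixed$decisions), 0L)
  expect_identical(vapply(rx_never$decisions, `[[`, "", "action"),
                   rep("continue", 2))
  for (field in c("n_randomised", "final_counts", "deaths_total",
                  "final_prob_superior", "accrual_duration", "successful")) {
    expect_identical(rx_fixed[[field]], rx_never[[field]])
  }
})

test_that("a symmetric stream ends at posterior one half", {
  n <- 200
  stream <- tibble::tibble(
    patient_id = sprintf("P%05d", 1:n),
    arm = rep(c("control", "treatment"), n / 2),
    recruit_week = seq(0.5, by = 0.5, length.out = n),
    outcome = rep(rep(c(1L, 0L), each = 2), n / 4)
  )
  d <- design_spec("sym", n_max = n)
  rx <- reexecute(stream, d, seed = 1)
  expect_equal(rx$final_prob_superior, 0.5, tolerance = 1e-10)
  expect_false(rx$successful)
})

test_that("a stream shorter than n_max is reported as truncated", {
  scn <- scenario_spec(0.45, 0.45)
  stream <- generate_stream(scn, 300, seed = 5)
  expect_warning(rx <- reexecute(stream, builtin_designs()$design1, seed = 1),
                 "short of n_max")
  expect_true(rx$truncated)
  expect_identical(rx$n_randomised, 300L)
})

test_that("design YAML round-trips exactly", {
  dir <- withr::local_tempdir()
  for (d in builtin_designs()[c("design1", "design2", "design5")]) {
    path <- file.path(dir, paste0(d$name, ".yaml"))
    write_design(d, path)
    d2 <- read_design(path)
    expect_equal(d2, d)
    # load -> dump -> load is bit-exact
    path2 <- file.path(dir, "again.yaml")
    write_design(d2, path2)
    expect_identical(readLines(path), readLines(path2))
    expect_equal(read_design(path2), d)
  }
  scn <- scenario_spec(0.45, 0.36, accrual_rate = 5.5, dropout = 0.03)
  ps <- file.path(dir, "scn.yaml")
  write_scenario(scn, ps)
  expect_equal(read_scenario(ps), scn)
})

test_that("patient CSV round-trips losslessly and validates on read", {
  dir <- withr::local_tempdir()
  scn <- scenario_spec(0.45, 0.36)
  stream <- generate_stream(scn, 250, seed = 31)
  path <- file.path(dir, "patients.csv")
  write_patients(stream, path)
  back <- read_patients(path)
  expect_identical(as.data.frame(back), as.data.frame(stream))

  bad <- stream
  bad$arm[3] <- "placebo"
  path_bad <- file.path(dir, "bad.csv")
  readr::write_csv(bad, path_bad, na = "NA")
  expect_error(read_patients(path_bad), "Row 3")
})
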