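# Whole-trial simulation under a scenario and aggregation of operating
# characteristics over many replicates.

#' Construct a trial scenario
#'
#' A scenario fixes the data-generating truth for simulated trials: the true
#' 30-day event (mortality) rates per arm, the mean accrual rate, the dropout
#' probability, and the follow-up length.
#'
#' @param p_control,p_treatment True event probabilities in (0, 1).
#' @param accrual_rate Mean recruitment rate, patients per week.
#' @param dropout Probability a randomised patient's outcome is never
#'   observed.
#' @param followup_days Follow-up length in days.
#' @param label Optional scenario label.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(0.45, 0.36, label = "target difference")
#' @export
scenario_spec <- function(p_control, p_treatment, accrual_rate = 5.5,
                          dropout = 0.03, followup_days = 30, label = NULL) {
  p_control <- check_prob(p_control, "p_control", open = c(TRUE, TRUE))
  p_treatment <- check_prob(p_treatment, "p_treatment", open = c(TRUE, TRUE))
  dropout <- check_prob(dropout, "dropout", open = c(FALSE, TRUE))
  if (!is.numeric(accrual_rate) || length(accrual_rate) != 1L || accrual_rate <= 0) {
    abort("`accrual_rate` must be a positive number of patients per week.")
  }
  followup_days <- check_count(followup_days, "followup_days", min = 1L)
  label <- label %||% sprintf("%g%% vs %g%%", 100 * p_control, 100 * p_treatment)
  structure(
    list(p_control = p_control, p_treatment = p_treatment,
         accrual_rate = as.numeric(accrual_rate), dropout = dropout,
         followup_days = followup_days, label = as.character(label)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: accrual %.2f/week, dropout %.1f%%, follow-up %d days\n",
              x$label, x$accrual_rate, 100 * x$dropout, x$followup_days))
  invisible(x)
}

#' Built-in evaluation scenarios
#'
#' The standard set of true-effect scenarios used to study the designs'
#' operating characteristics: no difference (the null), the 9% target
#' reduction, a small (5%) and a large (15%) reduction, and a harmful (5%
#' increase) effect, all against the same control rate. Accrual defaults to
#' 5.5 patients/week with 3% dropout and 30-day follow-up.
#'
#' @param p_control Control-arm event rate shared by all scenarios.
#' @param accrual_rate,dropout Passed to [scenario_spec()].
#' @return Named list of [scenario_spec()] objects: `no_difference`,
#'   `target`, `small`, `large`, `harmful`.
#' @export
builtin_scenarios <- function(p_control = 0.45, accrual_rate = 5.5, dropout = 0.03) {
  mk <- function(p_t, lab) {
    scenario_spec(p_control, p_t, accrual_rate = accrual_rate, dropout = dropout,
                  label = sprintf("%s: %g%% vs %g%%", lab, 100 * p_control, 100 * p_t))
  }
  list(
    no_difference = mk(p_control, "No difference"),
    target = mk(p_control - 0.09, "Target difference"),
    small = mk(p_control - 0.05, "Small difference"),
    large = mk(p_control - 0.15, "Large difference"),
    harmful = mk(p_control + 0.05, "Treatment harmful")
  )
}

#' Simulate one trial under a design and scenario
#'
#' Generates a patient stream from the scenario (Poisson-process accrual,
#' fair-coin 1:1 allocation, Bernoulli outcomes, independent dropout),
#' replays the design over it with [reexecute()], and summarises the result.
#' Trial duration is the accrual end plus follow-up for completed and
#' success-stopped trials; for futility stops the trial ceases immediately
#' at the trigger patient's recruitment time.
#'
#' @param design A [design_spec()].
#' @param scenario A [scenario_spec()].
#' @param seed Integer seed (required; one trial is one seeded replicate).
#' @param n_draws Monte-Carlo imputations per interim predictive
#'   probability.
#' @return A one-row tibble: `stop_reason` (`"success_stop"`,
#'   `"futility_stop"`, `"completed"`), `n_randomised`, `duration_weeks`,
#'   `successful`, `deaths`.
#' @export
simulate_trial <- function(design, scenario, seed, n_draws = 10000) {
  stopifnot(inherits(design, "design_spec"), inherits(scenario, "scenario_spec"))
  seed <- check_seed(seed, required = TRUE)
  seeds <- derive_seeds(seed, 2L)
  stream <- generate_stream(scenario, design$n_max, seed = seeds[1])
  rep_ <- reexecute(stream, design, n_draws = n_draws, seed = seeds[2],
                    dropout = scenario$dropout,
                    followup_days = scenario$followup_days)
  duration <- if (rep_$stop_reason == "futility_stop") {
    rep_$accrual_duration
  } else {
    rep_$accrual_duration + followup_weeks(scenario$followup_days)
  }
  tibble::tibble(
    stop_reason = rep_$stop_reason,
    n_randomised = rep_$n_randomised,
    duration_weeks = duration,
    successful = rep_$successful,
    deaths = rep_$deaths_total
  )
}

# Shared replicate loop; trial_seeds fixed up front so threshold grids can
# reuse common random numbers.
oc_run <- function(design, scenario, trial_seeds, n_draws) {
  purrr::map_dfr(trial_seeds, function(s) {
    simulate_trial(design, scenario, seed = s, n_draws = n_draws)
  })
}

#' Operating characteristics of a design under a scenario
#'
#' Aggregates `n_sims` independent [simulate_trial()] replicates. Replicate
#' seeds are derived from the master `seed` up front, so results are
#' reproducible and independent of evaluation order. Under the
#' no-difference scenario the proportion successful is the (one-sided)
#' simulated type I error; under the target-difference scenario it is the
#' power.
#'
#' @param design A [design_spec()].
#' @param scenario A [scenario_spec()].
#' @param n_sims Number of simulated trials.
#' @param seed Master seed.
#' @param n_draws Monte-Carlo imputations per interim predictive
#'   probability.
#' @return An `oc_table`: a one-row tibble with `design`, `scenario`,
#'   `mean_n`, `sd_n`, `mean_duration_weeks`, `prop_stop_success`,
#'   `prop_stop_futility`, `prop_successful`, Monte-Carlo standard errors
#'   (`mcse_*`), `n_sims`, `seed`, `n_draws`; the per-trial results are
#'   attached as attribute `"trials"`.
#' @export
operating_characteristics <- function(design, scenario, n_sims, seed,
                                      n_draws = 10000) {
  n_sims <- check_count(n_sims, "n_sims", min = 1L)
  seed <- check_seed(seed, required = TRUE)
  trial_seeds <- derive_seeds(seed, n_sims)
  trials <- oc_run(design, scenario, trial_seeds, n_draws)
  new_oc_table(design, scenario, trials, n_sims, seed, n_draws)
}

new_oc_table <- function(design, scenario, trials, n_sims, seed, n_draws) {
  prop_se <- function(p) sqrt(p * (1 - p) / n_sims)
  p_suc <- mean(trials$stop_reason == "success_stop")
  p_fut <- mean(trials$stop_reason == "futility_stop")
  p_win <- mean(trials$successful)
  out <- tibble::tibble(
    design = design$name,
    scenario = scenario$label,
    mean_n = mean(trials$n_randomised),
    sd_n = sd(trials$n_randomised),
    mean_duration_weeks = mean(trials$duration_weeks),
    prop_stop_success = p_suc,
    prop_stop_futility = p_fut,
    prop_successful = p_win,
    mcse_mean_n = sd(trials$n_randomised) / sqrt(n_sims),
    mcse_prop_stop_success = prop_se(p_suc),
    mcse_prop_stop_futility = prop_se(p_fut),
    mcse_prop_successful = prop_se(p_win),
    n_sims = n_sims,
    seed = seed,
    n_draws = n_draws
  )
  structure(out, trials = trials, class = c("oc_table", class(out)))
}

#' @export
print.oc_table <- function(x, ...) {
  cat(sprintf("Operating characteristics: %s under %s (%d simulated trials)\n",
              x$design, x$scenario, x$n_sims))
  cat(sprintf("  mean n = %.0f (sd %.0f), mean duration = %.0f weeks\n",
              x$mean_n, x$sd_n, x$mean_duration_weeks))
  cat(sprintf("  stopped early: success %.4f, futility %.4f; overall successful %.4f (MC se %.4f)\n",
              x$prop_stop_success, x$prop_stop_futility, x$prop_successful,
              x$mcse_prop_successful))
  invisible(x)
}

#' Calibrate stopping thresholds over a grid
#'
#' Evaluates every combination of candidate success and futility boundary
#' vectors over a set of scenarios, using common random numbers (the same
#' replicate seeds for every grid point) so grid points differ only through
#' their thresholds. Candidates are flagged when their simulated type I
#' error (proportion successful under a scenario with
#' `p_control == p_treatment`) is at most `type1_cap` and their power
#' (proportion successful under the first scenario with a true reduction)
#' is at least `power_floor`.
#'
#' @param design A [design_spec()] template whose interim schedule is reused
#'   for every candidate.
#' @param s_grid,f_grid Lists of per-interim success / futility threshold
#'   vectors (scalars are recycled across interims; `NA` entries in a
#'   success vector disable success stopping at that interim).
#' @param scenarios List of [scenario_spec()] objects; include a null
#'   scenario for type I error and an effect scenario for power.
#' @param n_sims,seed,n_draws Simulation settings shared by all grid points.
#' @param type1_cap,power_floor Acceptance bounds used for flagging.
#' @return A tibble with one row per candidate x scenario: the threshold
#'   vectors (list-columns `success_thresholds`, `futility_thresholds`),
#'   the OC columns of [operating_characteristics()], plus per-candidate
#'   `type1`, `power`, and `flagged`.
#' @export
calibrate_thresholds <- function(design, s_grid, f_grid, scenarios,
                                 n_sims, seed, n_draws = 10000,
                                 type1_cap = 0.03, power_floor = 0.78) {
  stopifnot(inherits(design, "design_spec"))
  if (!length(s_grid) || !length(f_grid)) abort("Threshold grids must be non-empty.")
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  n_int <- nrow(design$interims)
  if (n_int == 0) abort("Threshold calibration needs a design with interim analyses.")
  expand_thr <- function(v) {
    if (length(v) == 1L) v <- rep(v, n_int)
    if (length(v) != n_int) abort("Threshold vectors must have one entry per interim.")
    v
  }
  trial_seeds <- derive_seeds(seed, check_count(n_sims, "n_sims", min = 1L))
  is_null_scn <- vapply(scenarios, function(s) s$p_control == s$p_treatment, logical(1))
  is_eff_scn <- vapply(scenarios, function(s) s$p_treatment < s$p_control, logical(1))

  rows <- list()
  for (s_thr in s_grid) {
    s_thr <- expand_thr(s_thr)
    for (f_thr in f_grid) {
      f_thr <- expand_thr(f_thr)
      cand <- design_spec(
        name = sprintf("%s [S=%s; F=%s]", design$name,
                       paste(ifelse(is.na(s_thr), "-", format(s_thr)), collapse = "/"),
                       paste(format(f_thr), collapse = "/")),
        n_max = design$n_max,
        interims = tibble::tibble(n = design$interims$n, success = s_thr, futility = f_thr),
        final_threshold = design$final_threshold,
        prior = design$prior, allocation = design$allocation
      )
      ocs <- purrr::map(scenarios, function(scn) {
        trials <- oc_run(cand, scn, trial_seeds, n_draws)
        new_oc_table(cand, scn, trials, length(trial_seeds), seed, n_draws)
      })
      tab <- dplyr::bind_rows(lapply(ocs, tibble::as_tibble))
      type1 <- if (any(is_null_scn)) tab$prop_successful[which(is_null_scn)[1]] else NA_real_
      power <- if (any(is_eff_scn)) tab$prop_successful[which(is_eff_scn)[1]] else NA_real_
      tab$success_thresholds <- rep(list(s_thr), nrow(tab))
      tab$futility_thresholds <- rep(list(f_thr), nrow(tab))
      tab$type1 <- type1
      tab$power <- power
      tab$flagged <- !is.na(type1) && !is.na(power) &&
        type1 <= type1_cap && power >= power_floor
      rows[[length(rows) + 1L]] <- tab
    }
  }
  dplyr::bind_rows(rows)
}
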