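# Synthetic patient streams: unconstrained scenario draws, and constrained
# fixtures whose interim snapshots reproduce specified counts exactly.

#' Generate a patient stream under a scenario
#'
#' Recruitment times follow a homogeneous Poisson process at the scenario's
#' mean accrual rate (exponential inter-arrival times, no ramp-up); arms are
#' assigned by independent fair coin; outcomes are Bernoulli draws at the
#' arm's true event rate; each patient is independently a dropout (outcome
#' `NA`) with the scenario's dropout probability. Outcomes are fixed at
#' generation time and only revealed to analyses once the follow-up window
#' has elapsed.
#'
#' @param scenario A [scenario_spec()].
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; the stream is deterministic given the seed.
#' @return A tibble with columns `patient_id`, `arm`, `recruit_week`,
#'   `outcome` (0 alive, 1 dead, `NA` dropout), in recruitment order.
#' @export
generate_stream <- function(scenario, n_patients, seed) {
  stopifnot(inherits(scenario, "scenario_spec"))
  n_patients <- check_count(n_patients, "n_patients", min = 1L)
  seed <- check_seed(seed, required = TRUE)
  with_seed0(seed, {
    weeks <- cumsum(rexp(n_patients, rate = scenario$accrual_rate))
    arm <- ifelse(rbinom(n_patients, 1L, 0.5) == 1L, "treatment", "control")
    p <- ifelse(arm == "treatment", scenario$p_treatment, scenario$p_control)
    outcome <- rbinom(n_patients, 1L, p)
    outcome[rbinom(n_patients, 1L, scenario$dropout) == 1L] <- NA_integer_
    tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n_patients)),
      arm = arm,
      recruit_week = weeks,
      outcome = as.integer(outcome)
    )
  })
}

#' Interim count constraint for fixture generation
#'
#' Pins the snapshot that [stream_snapshot()] must produce when the
#' `at_total`-th patient is randomised: the per-arm randomised split, the
#' per-arm number of complete primary outcomes, and the deaths among them.
#'
#' @param at_total Trigger recruit count (both arms).
#' @param randomised_control,randomised_treatment Per-arm randomised counts
#'   (must sum to `at_total`).
#' @param complete_control,complete_treatment Per-arm complete-outcome
#'   counts at the trigger.
#' @param deaths_control,deaths_treatment Deaths among the complete.
#' @return An object of class `count_constraint`.
#' @export
count_constraint <- function(at_total, randomised_control, randomised_treatment,
                             complete_control, complete_treatment,
                             deaths_control, deaths_treatment) {
  snap <- interim_snapshot(randomised_control, randomised_treatment,
                           complete_control, complete_treatment,
                           deaths_control, deaths_treatment)
  at_total <- check_count(at_total, "at_total", min = 1L)
  if (sum(snap$randomised) != at_total) {
    abort(sprintf("Constraint at %d: per-arm randomised counts sum to %d.",
                  at_total, sum(snap$randomised)))
  }
  structure(c(list(at_total = at_total), unclass(snap)), class = "count_constraint")
}

#' @export
print.count_constraint <- function(x, ...) {
  cat(sprintf("Counts at n = %d: control %d randomised %d/%d, treatment %d randomised %d/%d\n",
              x$at_total,
              x$randomised[["control"]], x$deaths[["control"]], x$complete[["control"]],
              x$randomised[["treatment"]], x$deaths[["treatment"]], x$complete[["treatment"]]))
  invisible(x)
}

# Per-arm assignment of patients to (block, role) slots. Blocks are the
# recruitment intervals between constrained triggers; within a block the
# "head" patients complete before the block's trigger and the "trailing"
# patients sit inside the trailing follow-up window. Returns a data frame
# with one row per patient: block, role (head/trailing), cohort (1..K
# = first complete at that trigger, K+1 = complete after the last trigger,
# 0 = dropout, -1 = scenario fill).
plan_arm <- function(arm, t, r, c, d, final_r, final_a, final_d, K) {
  ineq <- function(fmt, ...) abort(sprintf(paste0("Infeasible constraints (%s arm): ", fmt), arm, ...))
  for (k in seq_len(K)) {
    if (k > 1) {
      if (r[k] < r[k - 1]) ineq("randomised decreases between triggers %d and %d.", k - 1, k)
      if (c[k] < c[k - 1]) ineq("complete decreases between triggers %d and %d.", k - 1, k)
      if (d[k] < d[k - 1]) ineq("deaths decrease between triggers %d and %d.", k - 1, k)
    }
  }
  if (!is.null(final_r)) {
    if (K && final_r < r[K]) ineq("final randomised %d below last trigger's %d.", final_r, r[K])
    if (K && final_a < c[K]) ineq("final analysed %d below last trigger's complete %d.", final_a, c[K])
    if (K && final_d < d[K]) ineq("final deaths %d below last trigger's %d.", final_d, d[K])
    if (final_a > final_r) ineq("final analysed %d exceeds randomised %d.", final_a, final_r)
    if (final_d > final_a) ineq("final deaths %d exceed analysed %d.", final_d, final_a)
  }
  coh <- diff(c(0L, c))                       # first complete at trigger k
  cohd <- diff(c(0L, d))
  post <- if (is.null(final_r)) 0L else final_a - (if (K) c[K] else 0L)
  drops <- if (is.null(final_r)) NA_integer_ else final_r - final_a
  blk <- diff(c(0L, r))                       # randomised in block k
  last_blk <- if (is.null(final_r)) NA_integer_ else final_r - (if (K) r[K] else 0L)
  if (any(cohd > coh)) {
    k <- which(cohd > coh)[1]
    ineq("deaths added at trigger %d exceed complete patients added.", k)
  }

  rows <- list()
  carry <- 0L  # cohort-(b+1) patients already placed in block b's trailing window
  drops_used <- 0L
  for (b in seq_len(K)) {
    head_b <- coh[b] - carry
    if (head_b < 0) ineq("complete at trigger %d below patients already in transit.", b)
    if (head_b > blk[b]) {
      ineq("complete at trigger %d (%d new) cannot fit the %d patients randomised in block %d.",
           b, coh[b], blk[b], b)
    }
    trailing_b <- blk[b] - head_b
    next_coh <- if (b < K) coh[b + 1] else post
    carry_next <- min(trailing_b, next_coh)
    fill <- trailing_b - carry_next
    # trailing slots not absorbed by the next completion cohort must be
    # patients that never complete (dropouts) or, with no final constraint,
    # scenario-filled patients behind the last trigger
    drop_b <- fill
    scen_b <- 0L
    if (is.na(drops)) {
      if (b == K) { scen_b <- fill; drop_b <- 0L }
    } else if (drops_used + drop_b > drops) {
      ineq("trigger %d leaves %d patients unresolved but only %d dropouts remain.",
           b, drop_b, drops - drops_used)
    }
    drops_used <- drops_used + drop_b
    rows[[b]] <- data.frame(
      block = b,
      role = rep(c("head", "trailing"), c(head_b, trailing_b)),
      cohort = c(rep(b, head_b), rep(b + 1L, carry_next),
                 rep(0L, drop_b), rep(-1L, scen_b))
    )
    carry <- carry_next
  }
  post_left <- post - (if (K) carry else 0L)
  if (!is.null(final_r)) {
    drops_left <- drops - drops_used
    if (post_left < 0) ineq("post-trigger analysed patients overfilled the last trailing window.")
    if (post_left + drops_left != last_blk) {
      ineq("final block needs %d patients but %d analysed + %d dropouts remain.",
           last_blk, post_left, drops_left)
    }
    if (last_blk > 0) {
      rows[[K + 1L]] <- data.frame(
        block = K + 1L, role = "trailing",
        cohort = c(rep(K + 1L, post_left), rep(0L, drops_left))
      )
    }
  }
  out <- do.call(rbind, rows)
  out$arm <- arm
  # deaths per completion cohort (cohort K+1 uses the final counts)
  deaths_by_cohort <- c(cohd, if (is.null(final_r)) 0L else final_d - (if (K) d[K] else 0L))
  attr(out, "deaths_by_cohort") <- deaths_by_cohort
  out
}

#' Generate a patient stream matching interim count constraints exactly
#'
#' Builds a recruitment stream whose [stream_snapshot()] at each constrained
#' trigger reproduces the constraint exactly: the per-arm randomised splits,
#' complete-outcome counts, and death counts. Completeness is controlled by
#' recruit-time placement: patients required to be complete at a trigger are
#' recruited at least one follow-up window before the trigger patient, while
#' in-transit patients are placed inside the trailing window. Patients in
#' the final denominators but absent from every complete count have their
#' outcomes revealed after the last trigger; patients absent from the final
#' denominators are dropouts. Recruitment times are evenly spaced within
#' these windows at the scenario's accrual rate, and arm order within each
#' window is shuffled deterministically by `seed`.
#'
#' With no constraints and no final counts this reduces to
#' [generate_stream()].
#'
#' @param constraints List of [count_constraint()]s at strictly increasing
#'   trigger totals.
#' @param final A [count_constraint()] describing the end of the stream:
#'   per-arm randomised counts, final analysed denominators (as `complete`)
#'   and deaths. `NULL` to fill everything after the last trigger from the
#'   scenario.
#' @param scenario A [scenario_spec()]; sets the accrual rate, follow-up
#'   length, and the distribution of any unconstrained patients.
#' @param n_patients Stream length when `final` is `NULL`.
#' @param seed Integer seed.
#' @return A patient tibble as from [generate_stream()].
#' @export
generate_fixture <- function(constraints = list(), final = NULL, scenario,
                             n_patients = NULL, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (inherits(constraints, "count_constraint")) constraints <- list(constraints)
  seed <- check_seed(seed, required = TRUE)
  if (!length(constraints) && is.null(final)) {
    if (is.null(n_patients)) abort("Provide `n_patients` when there are no constraints.")
    return(generate_stream(scenario, n_patients, seed))
  }
  for (cc in constraints) stopifnot(inherits(cc, "count_constraint"))
  if (!is.null(final)) stopifnot(inherits(final, "count_constraint"))
  K <- length(constraints)
  t <- vapply(constraints, `[[`, integer(1), "at_total")
  if (K > 1 && any(diff(t) <= 0)) abort("Constraint triggers must be strictly increasing.")
  N <- if (!is.null(final)) final$at_total else check_count(n_patients, "n_patients", min = 1L)
  if (K && N < t[K]) abort("Stream end precedes the last constrained trigger.")

  pick <- function(cc, field, arm) cc[[field]][[arm]]
  plans <- lapply(c("control", "treatment"), function(arm) {
    plan_arm(
      arm = arm, t = t,
      r = vapply(constraints, pick, integer(1), field = "randomised", arm = arm),
      c = vapply(constraints, pick, integer(1), field = "complete", arm = arm),
      d = vapply(constraints, pick, integer(1), field = "deaths", arm = arm),
      final_r = if (!is.null(final)) pick(final, "randomised", arm),
      final_a = if (!is.null(final)) pick(final, "complete", arm),
      final_d = if (!is.null(final)) pick(final, "deaths", arm),
      K = K
    )
  })
  names(plans) <- c("control", "treatment")
  both <- rbind(plans$control, plans$treatment)
  for (b in seq_len(K)) {
    if (!any(both$block == b & both$role == "trailing")) {
      abort(sprintf(
        "Infeasible constraints: trigger patient %d would need a complete outcome at its own randomisation.",
        b))
    }
  }

  lag <- followup_weeks(scenario$followup_days)
  margin <- min(0.05, lag / 10)
  rate <- scenario$accrual_rate
  T_trig <- t / rate
  if (K && any(diff(c(0, T_trig)) <= lag + 2 * margin)) {
    b <- which(diff(c(0, T_trig)) <= lag + 2 * margin)[1]
    abort(sprintf(
      "Infeasible constraints: interval before trigger %d is shorter than the follow-up window at %.2f patients/week.",
      b, rate))
  }

  with_seed0(seed, {
    all_pat <- rbind(plans$control, plans$treatment)
    if (is.null(final)) {
      extra <- N - (if (K) t[K] else 0L)
      if (extra > 0) {
        all_pat <- rbind(all_pat, data.frame(
          block = K + 1L, role = "trailing", cohort = -1L,
          arm = ifelse(rbinom(extra, 1L, 0.5) == 1L, "treatment", "control")
        ))
      }
    }
    # deaths within each completion cohort, shuffled across that cohort
    all_pat$outcome <- NA_integer_
    for (arm in c("control", "treatment")) {
      dbc <- attr(plans[[arm]], "deaths_by_cohort")
      for (ch in seq_along(dbc)) {
        idx <- which(all_pat$arm == arm & all_pat$cohort == ch)
        out <- rep(0L, length(idx))
        if (dbc[ch] > 0) out[sample.int(length(idx), dbc[ch])] <- 1L
        all_pat$outcome[idx] <- out
      }
      sc_idx <- which(all_pat$arm == arm & all_pat$cohort == -1L)
      if (length(sc_idx)) {
        p <- if (arm == "control") scenario$p_control else scenario$p_treatment
        out <- rbinom(length(sc_idx), 1L, p)
        out[rbinom(length(sc_idx), 1L, scenario$dropout) == 1L] <- NA_integer_
        all_pat$outcome[sc_idx] <- out
      }
    }
    all_pat$outcome[all_pat$cohort == 0L] <- NA_integer_

    # order: per block, shuffled head patients then shuffled trailing ones
    pieces <- list()
    n_blocks <- max(all_pat$block)
    for (b in seq_len(n_blocks)) {
      for (role in c("head", "trailing")) {
        grp <- all_pat[all_pat$block == b & all_pat$role == role, ]
        if (!nrow(grp)) next
        grp <- grp[sample.int(nrow(grp)), ]
        lo_hi <- if (role == "head") {
          c(if (b == 1) 0 else T_trig[b - 1], T_trig[b] - lag - margin)
        } else if (b <= K) {
          c(T_trig[b] - lag + margin, T_trig[b])
        } else {
          c(if (K) T_trig[K] else 0, N / rate)
        }
        grp$recruit_week <- lo_hi[1] + seq_len(nrow(grp)) * (lo_hi[2] - lo_hi[1]) / nrow(grp)
        pieces[[length(pieces) + 1L]] <- grp
      }
    }
    res <- do.call(rbind, pieces)
    tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(nrow(res))),
      arm = res$arm,
      recruit_week = res$recruit_week,
      outcome = res$outcome
    )
  })
}

#' Verify a stream against its count constraints
#'
#' Independently recounts the snapshot at every constrained trigger (and the
#' final counts, if given) and compares field by field.
#'
#' @param patients Patient tibble.
#' @param constraints List of [count_constraint()]s.
#' @param final Optional final [count_constraint()].
#' @param followup_days Follow-up length in days.
#' @return A tibble with one row per (trigger, arm, field): `expected`,
#'   `observed`, `match`.
#' @export
verify_fixture <- function(patients, constraints = list(), final = NULL,
                           followup_days = 30) {
  if (inherits(constraints, "count_constraint")) constraints <- list(constraints)
  rows <- list()
  add <- function(at, arm, field, expected, observed) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      at_total = at, arm = arm, field = field,
      expected = as.integer(expected), observed = as.integer(observed),
      match = expected == observed
    )
  }
  for (cc in constraints) {
    snap <- stream_snapshot(patients, cc$at_total, followup_days = followup_days)
    for (arm in c("control", "treatment")) {
      add(cc$at_total, arm, "randomised", cc$randomised[[arm]], snap$randomised[[arm]])
      add(cc$at_total, arm, "complete", cc$complete[[arm]], snap$complete[[arm]])
      add(cc$at_total, arm, "deaths", cc$deaths[[arm]], snap$deaths[[arm]])
    }
  }
  if (!is.null(final)) {
    sub <- patients[seq_len(final$at_total), ]
    for (arm in c("control", "treatment")) {
      in_arm <- sub$arm == arm
      add(final$at_total, arm, "final_randomised", final$randomised[[arm]], sum(in_arm))
      add(final$at_total, arm, "final_analysed", final$complete[[arm]],
          sum(in_arm & !is.na(sub$outcome)))
      add(final$at_total, arm, "final_deaths", final$deaths[[arm]],
          sum(in_arm & !is.na(sub$outcome) & sub$outcome == 1))
    }
  }
  dplyr::bind_rows(rows)
}

#' Observed OSCAR interim and final counts
#'
#' The per-arm randomised, complete-outcome and death counts observed in the
#' OSCAR trial (conventional ventilation vs high-frequency oscillatory
#' ventilation in ARDS; 795 patients randomised, 30-day mortality endpoint)
#' when its recruitment stream is monitored at the interim schedules of the
#' built-in sequential designs, together with the final counts after full
#' follow-up of everyone randomised by the stopping trigger. These pin down
#' constrained fixtures (see [oscar_fixture()]) for exercising the
#' re-execution engine without patient-level data.
#'
#' @param design One of `"design2"`, `"design3"`, `"design4"`, `"design5"`,
#'   or `"oscar"` (the full 795-patient trial with no interim constraints).
#' @return A list with elements `constraints` (list of
#'   [count_constraint()]), `final` ([count_constraint()]) and `design`.
#' @export
oscar_counts <- function(design = c("design2", "design3", "design4", "design5", "oscar")) {
  design <- match.arg(design)
  cc <- function(at, rc, rt, cc_, ct, dc, dt) {
    count_constraint(at, rc, rt, cc_, ct, dc, dt)
  }
  snap2 <- list( # schedule 250/500/750
    cc(250, 129, 121, 118, 113, 49, 44),
    cc(500, 249, 251, 230, 239, 96, 93),
    cc(750, 377, 373, 372, 363, 154, 152)
  )
  snap335 <- cc(335, 174, 161, 165, 153, 70, 57)
  snap670 <- cc(670, 339, 331, 330, 322, 136, 129)
  out <- switch(design,
    design2 = list(constraints = snap2,
                   final = cc(750, 377, 373, 377, 373, 154, 156)),
    design3 = list(constraints = list(snap335, snap670),
                   final = cc(670, 339, 331, 339, 331, 138, 134)),
    design4 = list(constraints = list(snap335, snap2[[2]], snap670),
                   final = cc(670, 339, 331, 339, 331, 138, 134)),
    design5 = list(constraints = list(
                     cc(503, 251, 252, 233, 240, 98, 93),
                     cc(755, 380, 375, 375, 364, 154, 152)),
                   final = cc(755, 380, 375, 380, 375, 156, 157)),
    oscar = list(constraints = list(),
                 final = cc(795, 397, 398, 397, 398, 163, 166))
  )
  c(out, list(design = design))
}

#' Constrained fixture stream for an OSCAR re-execution
#'
#' Convenience wrapper: builds the [generate_fixture()] stream for the
#' counts returned by [oscar_counts()].
#'
#' @param design Passed to [oscar_counts()].
#' @param seed Integer seed for the deterministic shuffles.
#' @param accrual_rate Accrual rate used to lay out recruitment times.
#' @return A patient tibble.
#' @export
oscar_fixture <- function(design = c("design2", "design3", "design4", "design5", "oscar"),
                          seed = 1L, accrual_rate = 5.5) {
  cnt <- oscar_counts(design)
  scn <- scenario_spec(0.45, 0.41, accrual_rate = accrual_rate, dropout = 0.03,
                       label = "fixture fill")
  generate_fixture(cnt$constraints, cnt$final, scn, seed = seed)
}
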