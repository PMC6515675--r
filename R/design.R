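# Sequential design specification, interim decision rules, and virtual
# re-execution of a design over a patient-level recruitment stream.

#' Construct a sequential design specification
#'
#' A design fixes the maximum sample size, the interim-analysis schedule (by
#' recruit count) with per-interim success boundaries `S_i` (on `P_curr`) and
#' futility boundaries `F_i` (on `P_max`), the final success threshold, the
#' per-arm prior, and the allocation ratio. A missing (`NA`) success boundary
#' means the trial cannot stop for success at that interim; a design with no
#' interims is a fixed design with a Bayesian final analysis.
#'
#' @param name Design label.
#' @param n_max Maximum sample size (both arms combined).
#' @param interims A data frame with columns `n` (strictly increasing recruit
#'   counts, all below `n_max`), `success` (`S_i`, `NA` where success
#'   stopping is not allowed) and `futility` (`F_i`). `NULL` for a fixed
#'   design.
#' @param final_threshold Final-analysis success threshold.
#' @param prior Per-arm prior, `c(alpha, beta)` or
#'   `list(control = , treatment = )`.
#' @param allocation Allocation weights `c(control, treatment)`.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec("halfway look", interims = data.frame(n = 503, success = 0.99, futility = 0.05))
#' @export
design_spec <- function(name, n_max = 1006, interims = NULL,
                        final_threshold = 0.975, prior = c(1, 1),
                        allocation = c(1, 1)) {
  n_max <- check_count(n_max, "n_max", min = 2L)
  final_threshold <- check_prob(final_threshold, "final_threshold", open = c(TRUE, TRUE))
  prior <- normalise_prior(prior)
  if (!is.numeric(allocation) || length(allocation) != 2L || any(allocation <= 0)) {
    abort("`allocation` must be two positive weights c(control, treatment).")
  }
  if (is.null(interims)) {
    interims <- tibble::tibble(n = integer(), success = double(), futility = double())
  }
  interims <- tibble::as_tibble(interims)
  if (!all(c("n", "success", "futility") %in% names(interims))) {
    abort("`interims` needs columns n, success, futility.")
  }
  interims <- interims[c("n", "success", "futility")]
  interims$n <- vapply(interims$n, check_count, integer(1), name = "interims$n", min = 1L)
  if (nrow(interims)) {
    if (any(diff(interims$n) <= 0)) abort("Interim schedule must be strictly increasing.")
    if (max(interims$n) >= n_max) abort("All interim recruit counts must be below n_max.")
    bad <- !is.na(interims$success) & (interims$success < 0 | interims$success > 1)
    if (any(bad) || any(interims$futility < 0 | interims$futility > 1, na.rm = TRUE)) {
      abort("Interim thresholds must lie in [0, 1].")
    }
    if (anyNA(interims$futility)) {
      abort("Each interim needs a futility threshold (use 0 to make it unreachable).")
    }
  }
  structure(
    list(name = as.character(name), n_max = n_max, interims = interims,
         final_threshold = final_threshold, prior = prior,
         allocation = as.numeric(allocation)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %s: n_max = %d, final threshold %.3f\n",
              x$name, x$n_max, x$final_threshold))
  if (nrow(x$interims) == 0) {
    cat("  fixed design (no interim analyses)\n")
  } else {
    for (i in seq_len(nrow(x$interims))) {
      cat(sprintf("  interim %d at n = %d: S = %s, F = %.3f\n",
                  i, x$interims$n[i],
                  ifelse(is.na(x$interims$success[i]), "-",
                         sprintf("%.3f", x$interims$success[i])),
                  x$interims$futility[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.design_spec <- function(x, ...) {
  dplyr::mutate(x$interims, design = x$name, interim = dplyr::row_number(),
                .before = 1)
}

#' Built-in candidate sequential designs
#'
#' The six candidate designs studied for the OSCAR trial (high-frequency
#' oscillatory ventilation versus conventional ventilation in ARDS, 30-day
#' mortality endpoint): a fixed design with a Bayesian final analysis plus
#' five sequential designs differing in the number and timing of interim
#' analyses and their success/futility boundaries. All share
#' `n_max = 1006`, a uniform `Beta(1, 1)` prior per arm, 1:1 allocation and
#' a 0.975 final success threshold.
#'
#' @return A named list of [design_spec()] objects
#'   (`design1` ... `design6`).
#' @examples
#' builtin_designs()$design5
#' @export
builtin_designs <- function() {
  mk <- function(id, n, S, F) {
    design_spec(
      name = id, n_max = 1006,
      interims = if (is.null(n)) NULL else tibble::tibble(n = n, success = S, futility = F)
    )
  }
  list(
    design1 = mk("Design 1", NULL, NULL, NULL),
    design2 = mk("Design 2", c(250L, 500L, 750L), c(NA, 0.99, 0.98), c(0.05, 0.10, 0.15)),
    design3 = mk("Design 3", c(335L, 670L), c(NA, 0.99), c(0.05, 0.10)),
    design4 = mk("Design 4", c(335L, 500L, 670L), c(NA, 0.99, 0.98), c(0.05, 0.10, 0.15)),
    design5 = mk("Design 5", c(503L, 755L), c(0.99, 0.98), c(0.05, 0.10)),
    design6 = mk("Design 6", c(503L, 755L, 880L), c(0.99, 0.98, 0.98), c(0.05, 0.10, 0.15))
  )
}

#' Apply the interim decision rules to a snapshot
#'
#' Computes `P_max` (always) and `P_curr` (only when the interim has a
#' success boundary) for the snapshot and applies the stopping rules:
#' stop for futility if `P_max < F_i`; otherwise stop for success if a
#' success boundary exists and `P_curr > S_i`; otherwise continue. Futility
#' is evaluated before success, so a trial that is predictively doomed at
#' the maximum sample size can never be stopped "for success"; the ordering
#' only matters in boundary cases.
#'
#' @param snapshot An [interim_snapshot()] whose randomised total matches the
#'   scheduled recruit count.
#' @param design A [design_spec()].
#' @param interim_index Which scheduled interim this is (1-based).
#' @param n_draws,seed Monte-Carlo settings passed to the predictive
#'   probability computations.
#' @param dropout Anticipated dropout probability for future patients in
#'   `P_max`.
#' @return An object of class `interim_decision`: `interim_index`, `action`
#'   (`"continue"`, `"stop_success"`, `"stop_futility"`), `p_superior`,
#'   `p_curr` (`NA` when no success boundary), `p_max`, `snapshot`.
#' @export
interim_decision <- function(snapshot, design, interim_index,
                             n_draws = 10000, seed = NULL, dropout = 0.03) {
  stopifnot(inherits(snapshot, "interim_snapshot"), inherits(design, "design_spec"))
  interim_index <- check_count(interim_index, "interim_index", min = 1L)
  if (interim_index > nrow(design$interims)) {
    abort(sprintf("Design '%s' has %d interims; index %d out of range.",
                  design$name, nrow(design$interims), interim_index))
  }
  sched_n <- design$interims$n[interim_index]
  if (sum(snapshot$randomised) != sched_n) {
    abort(sprintf("Snapshot has %d randomised patients but interim %d is scheduled at %d.",
                  sum(snapshot$randomised), interim_index, sched_n))
  }
  s_i <- design$interims$success[interim_index]
  f_i <- design$interims$futility[interim_index]
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(derive_seeds(seed, 2L))
  p_sup <- post_prob_counts(snapshot$deaths[["control"]], snapshot$complete[["control"]],
                            snapshot$deaths[["treatment"]], snapshot$complete[["treatment"]],
                            prior = design$prior)
  p_max <- predictive_prob_max(snapshot, n_max = design$n_max, prior = design$prior,
                               allocation = design$allocation, dropout = dropout,
                               final_threshold = design$final_threshold,
                               n_draws = n_draws, seed = seeds[[1]])
  p_curr <- if (!is.na(s_i)) {
    predictive_prob_current(snapshot, prior = design$prior,
                            final_threshold = design$final_threshold,
                            n_draws = n_draws, seed = seeds[[2]])
  }
  action <- if (p_max$probability < f_i) {
    "stop_futility"
  } else if (!is.na(s_i) && p_curr$probability > s_i) {
    "stop_success"
  } else {
    "continue"
  }
  structure(
    list(interim_index = interim_index, action = action,
         p_superior = p_sup,
         p_curr = if (is.null(p_curr)) NA_real_ else p_curr$probability,
         p_max = p_max$probability,
         snapshot = snapshot),
    class = "interim_decision"
  )
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("Interim %d: %s (P(sup) = %.4f, P_curr = %s, P_max = %.4f)\n",
              x$interim_index, x$action, x$p_superior,
              ifelse(is.na(x$p_curr), "-", sprintf("%.4f", x$p_curr)), x$p_max))
  invisible(x)
}

#' Virtually re-execute a sequential design over a patient stream
#'
#' Replays the design's decision rules over an existing patient-level
#' recruitment stream: at each scheduled recruit count the interim snapshot
#' is built from the patients whose follow-up window has elapsed by the
#' trigger patient's recruitment time (missing outcomes count as randomised
#' but never complete) and [interim_decision()] is applied. On an early stop
#' - or when the schedule is exhausted and the stream reaches `n_max` - all
#' randomised patients' follow-up is completed and the final analysis run:
#' posterior probability of superiority, relative risk, and death counts.
#' After a futility stop the trial is unsuccessful regardless of the final
#' posterior; accrual is assumed to cease immediately, so the accrual
#' duration is the trigger patient's recruitment time.
#'
#' @param patients Patient tibble (see [stream_snapshot()] for the required
#'   columns), sorted by recruitment time; simultaneous recruits are ordered
#'   by `patient_id`.
#' @param design A [design_spec()].
#' @param n_draws,seed Monte-Carlo settings for the interim predictive
#'   probabilities.
#' @param dropout Anticipated dropout probability used inside `P_max`.
#' @param followup_days Follow-up length in days.
#' @return An object of class `reexecution`; see [tidy.reexecution()] and
#'   [glance.reexecution()] for tabular views.
#' @export
reexecute <- function(patients, design, n_draws = 10000, seed = NULL,
                      dropout = 0.03, followup_days = 30) {
  stopifnot(inherits(design, "design_spec"))
  validate_patients(patients)
  ord <- order(patients$recruit_week, patients$patient_id)
  patients <- patients[ord, ]
  n_stream <- nrow(patients)
  n_interims <- nrow(design$interims)
  seeds <- if (is.null(seed)) rep(list(NULL), max(n_interims, 1L)) else
    as.list(derive_seeds(seed, max(n_interims, 1L)))

  decisions <- vector("list", n_interims)
  stopped_at <- NA_integer_
  stop_reason <- "completed"
  n_randomised <- min(design$n_max, n_stream)
  truncated <- FALSE

  for (i in seq_len(n_interims)) {
    k <- design$interims$n[i]
    if (k > n_stream) break
    snap <- stream_snapshot(patients, k, followup_days = followup_days)
    dec <- interim_decision(snap, design, i, n_draws = n_draws,
                            seed = seeds[[i]], dropout = dropout)
    decisions[[i]] <- dec
    if (dec$action != "continue") {
      stopped_at <- i
      stop_reason <- if (dec$action == "stop_futility") "futility_stop" else "success_stop"
      n_randomised <- k
      break
    }
  }
  decisions <- decisions[!vapply(decisions, is.null, logical(1))]
  truncated <- is.na(stopped_at) && n_stream < design$n_max
  if (truncated) {
    warn(sprintf("Stream has %d patients, short of n_max = %d; final analysis uses all %d.",
                 n_stream, design$n_max, n_randomised))
  }

  final_set <- patients[seq_len(n_randomised), ]
  analysed <- final_set[!is.na(final_set$outcome), ]
  ctrl <- analysed$arm == "control"
  d_c <- sum(analysed$outcome[ctrl] == 1)
  n_c <- sum(ctrl)
  d_t <- sum(analysed$outcome[!ctrl] == 1)
  n_t <- sum(!ctrl)
  prob_sup <- post_prob_counts(d_c, n_c, d_t, n_t, prior = design$prior)
  rr <- tryCatch(relative_risk(d_t, n_t, d_c, n_c),
                 error = function(e) tibble::tibble(rr = NA_real_, ci_low = NA_real_,
                                                    ci_high = NA_real_, level = 0.95))
  successful <- stop_reason != "futility_stop" && prob_sup > design$final_threshold

  structure(
    list(
      design = design,
      decisions = decisions,
      stopped_at = stopped_at,
      stop_reason = stop_reason,
      n_randomised = n_randomised,
      truncated = truncated,
      final_counts = c(deaths_control = d_c, analysed_control = n_c,
                       deaths_treatment = d_t, analysed_treatment = n_t),
      deaths_total = d_c + d_t,
      final_prob_superior = prob_sup,
      final_rr = rr,
      successful = successful,
      accrual_duration = final_set$recruit_week[[n_randomised]],
      n_draws = n_draws,
      seed = seed
    ),
    class = "reexecution"
  )
}

#' @export
print.reexecution <- function(x, ...) {
  cat(sprintf("<reexecution> %s\n", x$design$name))
  for (d in x$decisions) print(d)
  cat(sprintf(
    "  %s at n = %d; deaths %d; control %d/%d, treatment %d/%d\n  final P(sup) = %.4f, RR %.2f (%.2f, %.2f); accrual %.1f weeks\n",
    x$stop_reason, x$n_randomised, x$deaths_total,
    x$final_counts[["deaths_control"]], x$final_counts[["analysed_control"]],
    x$final_counts[["deaths_treatment"]], x$final_counts[["analysed_treatment"]],
    x$final_prob_superior, x$final_rr$rr, x$final_rr$ci_low, x$final_rr$ci_high,
    x$accrual_duration))
  invisible(x)
}
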