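# broom-style views of fitted/derived objects.

#' Tidy the interim decision trail of a re-execution
#'
#' @param x A `reexecution` from [reexecute()].
#' @param ... Unused.
#' @return One row per interim analysis: trigger count, per-arm allocation
#'   and complete-outcome counts, posterior probability of superiority,
#'   `P_curr` (`NA` where the interim has no success boundary), `P_max`,
#'   and the decision taken.
#' @exportS3Method generics::tidy
tidy.reexecution <- function(x, ...) {
  purrr::map_dfr(x$decisions, function(d) {
    tibble::tibble(
      design = x$design$name,
      interim = d$interim_index,
      n_trigger = sum(d$snapshot$randomised),
      randomised_control = d$snapshot$randomised[["control"]],
      randomised_treatment = d$snapshot$randomised[["treatment"]],
      deaths_control = d$snapshot$deaths[["control"]],
      complete_control = d$snapshot$complete[["control"]],
      deaths_treatment = d$snapshot$deaths[["treatment"]],
      complete_treatment = d$snapshot$complete[["treatment"]],
      p_superior = d$p_superior,
      p_curr = d$p_curr,
      p_max = d$p_max,
      decision = d$action
    )
  })
}

#' One-row summary of a re-execution's final analysis
#'
#' @param x A `reexecution` from [reexecute()].
#' @param ... Unused.
#' @return A one-row tibble: stop reason, number randomised, recruitment
#'   savings versus the design maximum, final counts, relative risk with
#'   interval, posterior probability of superiority, total deaths, success
#'   flag, and accrual duration in weeks.
#' @exportS3Method generics::glance
glance.reexecution <- function(x, ...) {
  tibble::tibble(
    design = x$design$name,
    stop_reason = x$stop_reason,
    stopped_at = x$stopped_at,
    n_randomised = x$n_randomised,
    savings_vs_n_max = x$design$n_max - x$n_randomised,
    deaths_control = x$final_counts[["deaths_control"]],
    analysed_control = x$final_counts[["analysed_control"]],
    deaths_treatment = x$final_counts[["deaths_treatment"]],
    analysed_treatment = x$final_counts[["analysed_treatment"]],
    deaths_total = x$deaths_total,
    rr = x$final_rr$rr,
    rr_ci_low = x$final_rr$ci_low,
    rr_ci_high = x$final_rr$ci_high,
    final_prob_superior = x$final_prob_superior,
    successful = x$successful,
    accrual_duration_weeks = x$accrual_duration,
    truncated = x$truncated
  )
}

#' Per-trial results behind an operating-characteristics summary
#'
#' @param x An `oc_table` from [operating_characteristics()].
#' @param ... Unused.
#' @return The per-trial tibble (`stop_reason`, `n_randomised`,
#'   `duration_weeks`, `successful`, `deaths`).
#' @exportS3Method generics::tidy
tidy.oc_table <- function(x, ...) {
  attr(x, "trials")
}

#' One-row operating-characteristics summary
#'
#' @param x An `oc_table`.
#' @param ... Unused.
#' @return The OC row as a plain tibble.
#' @exportS3Method generics::glance
glance.oc_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "oc_table")
  out
}
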