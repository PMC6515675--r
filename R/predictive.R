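# Posterior predictive probabilities of end-of-trial success.
#
# P_curr: probability that the trial succeeds at the *current* sample size
# once all enrolled patients complete follow-up (drives success stopping).
# P_max: probability that the trial succeeds if recruitment continues to the
# maximum sample size (drives futility stopping).
#
# Both integrate over parameter uncertainty: each imputation first draws the
# arm event rates from their current posteriors and then outcomes for the
# unresolved patients, i.e. the beta-binomial posterior predictive, not a
# plug-in binomial. When the number of unresolved patients is small the
# probability is computed by exact enumeration instead of Monte Carlo.

new_predictive_result <- function(probability, kind, method, n_draws, seed) {
  structure(
    list(probability = probability, kind = kind, method = method,
         n_draws = n_draws, seed = seed,
         mc_se = if (method == "monte_carlo") {
           sqrt(probability * (1 - probability) / n_draws)
         } else 0),
    class = "predictive_result"
  )
}

#' @export
print.predictive_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  [%s%s]\n", x$kind, x$probability, x$method,
              if (x$method == "monte_carlo") {
                sprintf(", %d draws, MC se %.4f", x$n_draws, x$mc_se)
              } else ""))
  invisible(x)
}

# Beta-binomial predictive pmf for k = 0..n events.
betabinom_pmf <- function(n, alpha, beta) {
  k <- 0:n
  exp(lchoose(n, k) + lbeta(alpha + k, beta + n - k) - lbeta(alpha, beta))
}

# Per-arm predictive distribution over (added_analysed, added_deaths) for
# `in_transit` enrolled patients (always eventually observed) plus `future`
# patients thinned by `dropout`. Returns a data frame with columns
# added_analysed, added_deaths, weight.
arm_completion_table <- function(in_transit, future, dropout, alpha, beta) {
  out <- vector("list", future + 1L)
  for (j in 0:future) {
    w_j <- if (future > 0) dbinom(j, future, 1 - dropout) else 1
    if (w_j == 0) next
    n_add <- in_transit + j
    out[[j + 1L]] <- data.frame(
      added_analysed = n_add,
      added_deaths = 0:n_add,
      weight = w_j * betabinom_pmf(n_add, alpha, beta)
    )
  }
  res <- do.call(rbind, out)
  res[res$weight > 0, , drop = FALSE]
}

# Shared engine for P_curr / P_max. future_c/future_t = 0 gives P_curr.
predictive_prob_impl <- function(snapshot, prior, final_threshold,
                                 future_c, future_t, dropout,
                                 n_draws, seed, enumerate_limit, kind) {
  stopifnot(inherits(snapshot, "interim_snapshot"))
  prior <- normalise_prior(prior)
  final_threshold <- check_prob(final_threshold, "final_threshold", open = c(TRUE, TRUE))
  m_c <- snapshot$randomised[["control"]] - snapshot$complete[["control"]]
  m_t <- snapshot$randomised[["treatment"]] - snapshot$complete[["treatment"]]
  d_c <- snapshot$deaths[["control"]]
  d_t <- snapshot$deaths[["treatment"]]
  n_c <- snapshot$complete[["control"]]
  n_t <- snapshot$complete[["treatment"]]
  a_c <- prior$control[1] + d_c
  b_c <- prior$control[2] + n_c - d_c
  a_t <- prior$treatment[1] + d_t
  b_t <- prior$treatment[2] + n_t - d_t
  outstanding <- m_c + m_t + future_c + future_t

  if (outstanding == 0) {
    prob <- as.numeric(final_success(d_c, n_c, d_t, n_t,
                                     prior = prior, threshold = final_threshold))
    return(new_predictive_result(prob, kind, "degenerate", 0L, NULL))
  }

  if (outstanding <= enumerate_limit) {
    tab_c <- arm_completion_table(m_c, future_c, dropout, a_c, b_c)
    tab_t <- arm_completion_table(m_t, future_t, dropout, a_t, b_t)
    grid <- expand.grid(ic = seq_len(nrow(tab_c)), it = seq_len(nrow(tab_t)))
    succ <- classify_success(
      deaths_c = d_c + tab_c$added_deaths[grid$ic],
      analysed_c = n_c + tab_c$added_analysed[grid$ic],
      deaths_t = d_t + tab_t$added_deaths[grid$it],
      analysed_t = n_t + tab_t$added_analysed[grid$it],
      prior = prior, threshold = final_threshold
    )
    prob <- sum(tab_c$weight[grid$ic] * tab_t$weight[grid$it] * succ)
    return(new_predictive_result(prob, kind, "enumeration", 0L, NULL))
  }

  seed <- check_seed(seed, required = TRUE)
  n_draws <- check_count(n_draws, "n_draws", min = 1L)
  prob <- with_seed0(seed, {
    p_c <- rbeta(n_draws, a_c, b_c)
    p_t <- rbeta(n_draws, a_t, b_t)
    j_c <- if (future_c > 0) rbinom(n_draws, future_c, 1 - dropout) else integer(n_draws)
    j_t <- if (future_t > 0) rbinom(n_draws, future_t, 1 - dropout) else integer(n_draws)
    k_c <- rbinom(n_draws, m_c + j_c, p_c)
    k_t <- rbinom(n_draws, m_t + j_t, p_t)
    succ <- classify_success(
      deaths_c = d_c + k_c, analysed_c = n_c + m_c + j_c,
      deaths_t = d_t + k_t, analysed_t = n_t + m_t + j_t,
      prior = prior, threshold = final_threshold
    )
    mean(succ)
  })
  new_predictive_result(prob, kind, "monte_carlo", n_draws, seed)
}

#' Predictive probability of success at the current sample size (P_curr)
#'
#' Posterior predictive probability that the trial would be declared
#' successful at its current sample size once every enrolled patient
#' completes follow-up. Each imputation draws the arm event rates from
#' their current posteriors and then binomial outcomes for the in-transit
#' patients (enrolled, outcome pending); the final success rule is applied
#' to the completed dataset. In-transit patients are imputed as eventually
#' observed - they are already enrolled and being followed.
#'
#' With at most `enumerate_limit` in-transit patients the probability is an
#' exact enumeration over the beta-binomial predictive; otherwise it is a
#' Monte-Carlo proportion over `n_draws` imputations (a `seed` is then
#' required).
#'
#' @param snapshot An [interim_snapshot()].
#' @param prior Per-arm prior, `c(alpha, beta)` or
#'   `list(control = , treatment = )`.
#' @param final_threshold Final-analysis success threshold (default 0.975).
#' @param n_draws Monte-Carlo imputations.
#' @param seed Integer seed (required on the Monte-Carlo path).
#' @param enumerate_limit Maximum number of unresolved patients for the
#'   exact-enumeration path (default 20).
#' @return A `predictive_result` with elements `probability`, `kind`
#'   (`"P_curr"`), `method`, `n_draws`, `seed`, `mc_se`.
#' @export
predictive_prob_current <- function(snapshot, prior = c(1, 1),
                                    final_threshold = 0.975,
                                    n_draws = 10000, seed = NULL,
                                    enumerate_limit = 20) {
  predictive_prob_impl(snapshot, prior, final_threshold,
                       future_c = 0L, future_t = 0L, dropout = 0,
                       n_draws = n_draws, seed = seed,
                       enumerate_limit = enumerate_limit, kind = "P_curr")
}

#' Predictive probability of success at the maximum sample size (P_max)
#'
#' Posterior predictive probability that the trial is declared successful at
#' the final analysis if recruitment continues to `n_max` patients. On top
#' of the in-transit imputation of [predictive_prob_current()], the
#' `n_max - randomised` future patients are allocated deterministically in
#' the `allocation` ratio (default 1:1, odd remainder to the control arm),
#' thinned by the anticipated `dropout` probability, and their outcomes
#' drawn from the same posterior predictive before the final success rule
#' is applied at the maximum sample size.
#'
#' @inheritParams predictive_prob_current
#' @param n_max Maximum sample size (total over both arms).
#' @param allocation Length-2 allocation weights `c(control, treatment)`.
#' @param dropout Probability that a future patient's outcome is never
#'   observed. In-transit patients are not thinned (see
#'   `dropout_in_transit`).
#' @param dropout_in_transit If `TRUE`, in-transit patients are also thinned
#'   by `dropout` (default `FALSE`: they are already enrolled and followed).
#' @return A `predictive_result` with `kind = "P_max"`.
#' @export
predictive_prob_max <- function(snapshot, n_max, prior = c(1, 1),
                                allocation = c(1, 1), dropout = 0.03,
                                final_threshold = 0.975,
                                n_draws = 10000, seed = NULL,
                                enumerate_limit = 20,
                                dropout_in_transit = FALSE) {
  stopifnot(inherits(snapshot, "interim_snapshot"))
  n_max <- check_count(n_max, "n_max", min = 1L)
  dropout <- check_prob(dropout, "dropout", open = c(FALSE, TRUE))
  randomised_total <- sum(snapshot$randomised)
  if (randomised_total > n_max) {
    abort(sprintf("Snapshot has %d randomised patients, more than n_max = %d.",
                  randomised_total, n_max))
  }
  if (!is.numeric(allocation) || length(allocation) != 2L || any(allocation <= 0)) {
    abort("`allocation` must be two positive weights c(control, treatment).")
  }
  future <- n_max - randomised_total
  future_c <- as.integer(ceiling(future * allocation[1] / sum(allocation)))
  future_t <- as.integer(future - future_c)
  snap <- snapshot
  if (dropout_in_transit) {
    # fold in-transit patients into the thinned "future" pool
    extra_c <- snap$randomised[["control"]] - snap$complete[["control"]]
    extra_t <- snap$randomised[["treatment"]] - snap$complete[["treatment"]]
    snap$randomised <- snap$complete
    future_c <- future_c + extra_c
    future_t <- future_t + extra_t
  }
  predictive_prob_impl(snap, prior, final_threshold,
                       future_c = future_c, future_t = future_t,
                       dropout = dropout,
                       n_draws = n_draws, seed = seed,
                       enumerate_limit = enumerate_limit, kind = "P_max")
}
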