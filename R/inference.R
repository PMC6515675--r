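# Conjugate beta-binomial inference for a two-arm binary-endpoint trial.

#' Beta posterior for one arm's event rate
#'
#' Conjugate update of a `Beta(prior_alpha, prior_beta)` prior on an arm's
#' 30-day event rate with `deaths` events among `analysed` patients with a
#' complete outcome. The default `Beta(1, 1)` prior is uniform: every event
#' rate between 0 and 100% is a priori equally likely.
#'
#' @param deaths Number of events (deaths) among analysed patients.
#' @param analysed Number of patients with a complete outcome.
#' @param prior_alpha,prior_beta Positive prior parameters.
#' @return An object of class `beta_posterior` with elements `alpha` and
#'   `beta` (`alpha = prior_alpha + deaths`,
#'   `beta = prior_beta + analysed - deaths`).
#' @examples
#' beta_posterior(49, 118) # Beta(50, 70)
#' @export
beta_posterior <- function(deaths, analysed, prior_alpha = 1, prior_beta = 1) {
  cnt <- check_arm_counts(deaths, analysed)
  if (!is.numeric(prior_alpha) || !is.numeric(prior_beta) ||
      length(prior_alpha) != 1L || length(prior_beta) != 1L ||
      is.na(prior_alpha) || is.na(prior_beta) ||
      prior_alpha <= 0 || prior_beta <= 0) {
    abort("Prior parameters must be single positive numbers.")
  }
  structure(
    list(alpha = prior_alpha + cnt[["deaths"]],
         beta = prior_beta + cnt[["analysed"]] - cnt[["deaths"]]),
    class = "beta_posterior"
  )
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior (mean %.4f)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

as_beta_posterior <- function(x, name) {
  if (inherits(x, "beta_posterior")) return(x)
  if (is.numeric(x) && length(x) == 2L && all(x > 0)) {
    return(structure(list(alpha = x[[1]], beta = x[[2]]), class = "beta_posterior"))
  }
  abort(sprintf("`%s` must be a beta_posterior or a positive length-2 numeric.", name))
}

# Exact finite-sum evaluation of P(X < Y), X ~ Beta(aT, bT), Y ~ Beta(aC, bC),
# valid when aC is a positive integer. Evaluated in log space for stability.
psup_closed_form <- function(aT, bT, aC, bC) {
  j <- seq.int(0L, aC - 1L)
  sum(exp(lbeta(aT + j, bT + bC) - log(bC + j) - lbeta(1 + j, bC) - lbeta(aT, bT)))
}

# Adaptive quadrature of P(X < Y) = E_Y[F_X(Y)] over the control density.
psup_quadrature <- function(aT, bT, aC, bC, tol) {
  res <- integrate(function(x) dbeta(x, aC, bC) * pbeta(x, aT, bT),
                   lower = 0, upper = 1,
                   rel.tol = .Machine$double.eps^0.5, abs.tol = tol / 10,
                   stop.on.error = FALSE)
  if (res$message != "OK" || res$abs.error > tol) {
    abort(sprintf("Quadrature for P(p_T < p_C) did not converge to tolerance %g (error %g).",
                  tol, res$abs.error))
  }
  min(max(res$value, 0), 1)
}

# Fast scalar P(p_T < p_C) used on hot paths: closed form when the control
# shape is integer, quadrature otherwise.
psup_scalar <- function(aT, bT, aC, bC, tol = 1e-10) {
  if (aC == floor(aC) && aC <= 50000) {
    psup_closed_form(aT, bT, aC, bC)
  } else {
    psup_quadrature(aT, bT, aC, bC, tol = max(tol, 1e-12))
  }
}

#' Posterior probability that the treatment arm has the lower event rate
#'
#' Computes `P(p_T < p_C)` for independent beta-distributed event rates
#' `p_T ~ Beta(alpha_T, beta_T)` (treatment) and `p_C ~ Beta(alpha_C, beta_C)`
#' (control). The event is continuous, so `P(p_T < p_C) + P(p_C < p_T) = 1`.
#'
#' Method `"closed_form"` evaluates the exact finite sum
#' \deqn{\sum_{j=0}^{\alpha_C - 1}
#'   \frac{B(\alpha_T + j, \beta_T + \beta_C)}
#'        {(\beta_C + j)\, B(1 + j, \beta_C)\, B(\alpha_T, \beta_T)}}
#' which requires an integer control shape `alpha_C`; `"quadrature"`
#' integrates the control density against the treatment CDF;
#' `"monte_carlo"` draws paired beta samples (retained mainly as an
#' independent check). `"auto"` picks the closed form when available,
#' quadrature otherwise.
#'
#' @param treatment,control `beta_posterior` objects (or length-2 numerics
#'   `c(alpha, beta)`).
#' @param method One of `"auto"`, `"closed_form"`, `"quadrature"`,
#'   `"monte_carlo"`.
#' @param tol Absolute error tolerance for the deterministic methods.
#' @param n_draws,seed Monte-Carlo settings (only used by `"monte_carlo"`).
#' @return An object of class `superiority_result`: a list with
#'   `prob_superior` and `method`.
#' @examples
#' prob_superiority(beta_posterior(93, 239), beta_posterior(96, 230))
#' @export
prob_superiority <- function(treatment, control,
                             method = c("auto", "closed_form", "quadrature", "monte_carlo"),
                             tol = 1e-8, n_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  post_t <- as_beta_posterior(treatment, "treatment")
  post_c <- as_beta_posterior(control, "control")
  aT <- post_t$alpha; bT <- post_t$beta
  aC <- post_c$alpha; bC <- post_c$beta
  if (method == "auto") {
    method <- if (aC == floor(aC) && aC <= 50000) "closed_form" else "quadrature"
  }
  prob <- switch(method,
    closed_form = {
      if (aC != floor(aC)) {
        abort("Closed-form evaluation requires an integer control shape `alpha`.")
      }
      psup_closed_form(aT, bT, aC, bC)
    },
    quadrature = psup_quadrature(aT, bT, aC, bC, tol),
    monte_carlo = {
      seed <- check_seed(seed)
      with_seed0(seed, mean(rbeta(n_draws, aT, bT) < rbeta(n_draws, aC, bC)))
    }
  )
  structure(list(prob_superior = prob, method = method),
            class = "superiority_result")
}

#' @export
print.superiority_result <- function(x, ...) {
  cat(sprintf("P(p_T < p_C) = %.6f  [%s]\n", x$prob_superior, x$method))
  invisible(x)
}

# Posterior probability of superiority straight from the four cell counts.
post_prob_counts <- function(deaths_c, analysed_c, deaths_t, analysed_t,
                             prior = c(1, 1)) {
  prior <- normalise_prior(prior)
  psup_scalar(prior$treatment[1] + deaths_t,
              prior$treatment[2] + analysed_t - deaths_t,
              prior$control[1] + deaths_c,
              prior$control[2] + analysed_c - deaths_c)
}

#' Final success rule
#'
#' The trial is successful at the final analysis when the posterior
#' probability that the treatment arm has the lower event rate exceeds
#' `threshold` (strictly; the default 0.975 mirrors a one-sided 2.5% level).
#'
#' @param deaths_control,analysed_control Control-arm counts.
#' @param deaths_treatment,analysed_treatment Treatment-arm counts.
#' @param prior Prior as `c(alpha, beta)` shared by both arms, or
#'   `list(control = , treatment = )`.
#' @param threshold Success threshold in (0, 1).
#' @return Logical scalar; the posterior probability is attached as
#'   attribute `"prob_superior"`.
#' @examples
#' final_success(163, 397, 166, 398) # FALSE
#' @export
final_success <- function(deaths_control, analysed_control,
                          deaths_treatment, analysed_treatment,
                          prior = c(1, 1), threshold = 0.975) {
  check_arm_counts(deaths_control, analysed_control, "control")
  check_arm_counts(deaths_treatment, analysed_treatment, "treatment")
  threshold <- check_prob(threshold, "threshold", open = c(TRUE, TRUE))
  prob <- post_prob_counts(deaths_control, analysed_control,
                           deaths_treatment, analysed_treatment, prior)
  structure(prob > threshold, prob_superior = prob)
}

#' Relative risk with a log-normal (Katz) confidence interval
#'
#' Point estimate `rr = (d_T/n_T) / (d_C/n_C)` with the standard interval on
#' the log scale,
#' `exp(log rr +/- z * sqrt(1/d_T - 1/n_T + 1/d_C - 1/n_C))`.
#' All four cells must be positive for the interval; no continuity
#' correction is applied.
#'
#' @param deaths_treatment,analysed_treatment Treatment-arm counts.
#' @param deaths_control,analysed_control Control-arm counts.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `rr`, `ci_low`, `ci_high`, `level`.
#' @examples
#' relative_risk(166, 398, 163, 397) # 1.02 (0.86, 1.20)
#' @export
relative_risk <- function(deaths_treatment, analysed_treatment,
                          deaths_control, analysed_control, level = 0.95) {
  check_arm_counts(deaths_treatment, analysed_treatment, "treatment")
  check_arm_counts(deaths_control, analysed_control, "control")
  level <- check_prob(level, "level", open = c(TRUE, TRUE))
  if (analysed_treatment == 0 || analysed_control == 0 || deaths_control == 0) {
    abort("Relative risk undefined: needs analysed patients in both arms and control deaths > 0.")
  }
  rr <- (deaths_treatment / analysed_treatment) / (deaths_control / analysed_control)
  if (deaths_treatment == 0 || deaths_treatment == analysed_treatment ||
      deaths_control == analysed_control) {
    abort("Relative-risk interval undefined with a zero cell; no continuity correction is applied.")
  }
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / deaths_treatment - 1 / analysed_treatment +
             1 / deaths_control - 1 / analysed_control)
  tibble::tibble(
    rr = rr,
    ci_low = exp(log(rr) - z * se),
    ci_high = exp(log(rr) + z * se),
    level = level
  )
}

#' Sample size for comparing two proportions (continuity corrected)
#'
#' Per-arm sample size for a two-sided test of two independent proportions
#' at level `alpha` with the given `power`, using the continuity-corrected
#' (Fleiss / Casagrande-Pike-Smith) formula
#' \deqn{n_{cc} = \frac{n'}{4}\left(1 + \sqrt{1 + \frac{4}{n' d}}\right)^2}
#' where `n'` is the uncorrected normal-approximation size and
#' `d` the absolute risk difference. The per-arm size is then inflated for
#' anticipated dropout by dividing by `1 - dropout` and taking the ceiling.
#'
#' @param p_control Control-arm event proportion.
#' @param absolute_reduction Absolute reduction under the alternative
#'   (treatment rate is `p_control - absolute_reduction`).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param dropout Anticipated proportion of randomised patients with no
#'   observed outcome.
#' @return A one-row tibble: `n_per_arm`, `n_total`, and the intermediate
#'   `n_uncorrected` and `n_corrected` values before dropout inflation.
#' @examples
#' sample_size_two_proportions(0.45, 0.09, dropout = 0.03) # 503 per arm
#' @export
sample_size_two_proportions <- function(p_control, absolute_reduction,
                                        alpha = 0.05, power = 0.80,
                                        dropout = 0) {
  p_control <- check_prob(p_control, "p_control", open = c(TRUE, TRUE))
  alpha <- check_prob(alpha, "alpha", open = c(TRUE, TRUE))
  power <- check_prob(power, "power", open = c(TRUE, TRUE))
  dropout <- check_prob(dropout, "dropout", open = c(FALSE, TRUE))
  p_treat <- p_control - absolute_reduction
  if (!is.numeric(absolute_reduction) || absolute_reduction <= 0 ||
      p_treat <= 0 || p_treat >= p_control) {
    abort("`absolute_reduction` must satisfy 0 < p_control - absolute_reduction < p_control.")
  }
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  d <- absolute_reduction
  p_bar <- (p_control + p_treat) / 2
  n_unc <- (z_a * sqrt(2 * p_bar * (1 - p_bar)) +
            z_b * sqrt(p_control * (1 - p_control) + p_treat * (1 - p_treat)))^2 / d^2
  n_cc <- n_unc / 4 * (1 + sqrt(1 + 4 / (n_unc * d)))^2
  n_arm <- as.integer(ceiling(n_cc / (1 - dropout)))
  tibble::tibble(
    n_per_arm = n_arm,
    n_total = 2L * n_arm,
    n_uncorrected = n_unc,
    n_corrected = n_cc
  )
}
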