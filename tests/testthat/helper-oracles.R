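# Independent oracles used by the tests. These deliberately take different
# computational routes from the package internals: per-sequence enumeration
# instead of binomial-coefficient aggregation, explicit loops instead of
# vectorised recounts, and the closed-form normal approximation for fixed
# designs.

# Brute-force posterior predictive probability of final success: enumerate
# every individual outcome sequence for the unresolved patients (in-transit
# plus future, no dropout), weight each specific sequence by its
# beta-binomial predictive mass B(a+k, b+m-k)/B(a, b), and apply the
# success rule via quadrature.
oracle_predictive <- function(randomised_c, randomised_t, complete_c, complete_t,
                              deaths_c, deaths_t, threshold,
                              future_c = 0, future_t = 0, prior = c(1, 1)) {
  m_c <- randomised_c - complete_c + future_c
  m_t <- randomised_t - complete_t + future_t
  a_c <- prior[1] + deaths_c; b_c <- prior[2] + complete_c - deaths_c
  a_t <- prior[1] + deaths_t; b_t <- prior[2] + complete_t - deaths_t
  seq_weight <- function(k, m, a, b) exp(lbeta(a + k, b + m - k) - lbeta(a, b))
  success <- function(dc, nc, dt, nt) {
    p <- prob_superiority(c(prior[1] + dt, prior[2] + nt - dt),
                          c(prior[1] + dc, prior[2] + nc - dc),
                          method = "quadrature")$prob_superior
    p > threshold
  }
  total <- 0
  for (cfg_c in 0:(2^m_c - 1)) {
    k_c <- sum(bitwAnd(cfg_c, bitwShiftL(1, seq_len(max(m_c, 1)) - 1)) > 0)
    if (m_c == 0) k_c <- 0
    w_c <- seq_weight(k_c, m_c, a_c, b_c)
    for (cfg_t in 0:(2^m_t - 1)) {
      k_t <- sum(bitwAnd(cfg_t, bitwShiftL(1, seq_len(max(m_t, 1)) - 1)) > 0)
      if (m_t == 0) k_t <- 0
      w_t <- seq_weight(k_t, m_t, a_t, b_t)
      if (success(deaths_c + k_c, complete_c + m_c,
                  deaths_t + k_t, complete_t + m_t)) {
        total <- total + w_c * w_t
      }
    }
  }
  total
}

# Loop-based recount of the snapshot at a trigger, independent of
# stream_snapshot()'s vectorised implementation.
recount_snapshot <- function(patients, at_n, followup_days = 30) {
  trigger_time <- patients$recruit_week[at_n]
  counts <- list(control = c(r = 0, c = 0, d = 0), treatment = c(r = 0, c = 0, d = 0))
  for (i in seq_len(at_n)) {
    arm <- patients$arm[i]
    counts[[arm]]["r"] <- counts[[arm]]["r"] + 1
    done <- patients$recruit_week[i] <= trigger_time - followup_days / 7 + 1e-9 &&
      !is.na(patients$outcome[i])
    if (done) {
      counts[[arm]]["c"] <- counts[[arm]]["c"] + 1
      if (patients$outcome[i] == 1) counts[[arm]]["d"] <- counts[[arm]]["d"] + 1
    }
  }
  counts
}

# Closed-form power of the fixed design at the normal approximation with a
# given per-arm effective sample size.
oracle_fixed_power <- function(p_c, p_t, n_eff) {
  se <- sqrt(p_c * (1 - p_c) / n_eff + p_t * (1 - p_t) / n_eff)
  pnorm((p_c - p_t) / se - qnorm(0.975))
}

expect_snapshot_equal <- function(snap, randomised, complete, deaths) {
  expect_identical(unname(as.integer(snap$randomised)), as.integer(randomised))
  expect_identical(unname(as.integer(snap$complete)), as.integer(complete))
  expect_identical(unname(as.integer(snap$deaths)), as.integer(deaths))
}
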