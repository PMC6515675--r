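# Internal helpers: argument checks, seeding, and the success-boundary cache.

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

check_prob <- function(x, name, open = c(FALSE, FALSE)) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    abort(sprintf("`%s` must be a single probability.", name))
  }
  lo_ok <- if (open[1]) x > 0 else x >= 0
  hi_ok <- if (open[2]) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in %s0, 1%s, got %g.",
                  name, if (open[1]) "(" else "[", if (open[2]) ")" else "]", x))
  }
  as.numeric(x)
}

check_arm_counts <- function(deaths, analysed, arm = "arm") {
  deaths <- check_count(deaths, paste0("deaths_", arm))
  analysed <- check_count(analysed, paste0("analysed_", arm))
  if (deaths > analysed) {
    abort(sprintf("Invalid counts for %s: deaths (%d) exceed analysed (%d).",
                  arm, deaths, analysed))
  }
  c(deaths = deaths, analysed = analysed)
}

# Normalise a prior specification to list(control = c(alpha, beta),
# treatment = c(alpha, beta)). Accepts a length-2 numeric shared by both
# arms, or a list with elements `control` and `treatment`.
normalise_prior <- function(prior) {
  if (is.numeric(prior) && length(prior) == 2L) {
    prior <- list(control = prior, treatment = prior)
  }
  if (!is.list(prior) || !all(c("control", "treatment") %in% names(prior))) {
    abort("`prior` must be c(alpha, beta) or list(control = , treatment = ).")
  }
  for (arm in c("control", "treatment")) {
    p <- prior[[arm]]
    if (length(p) != 2L || !is.numeric(p) || any(is.na(p)) || any(p <= 0)) {
      abort(sprintf("Prior parameters for the %s arm must be two positive numbers.", arm))
    }
    prior[[arm]] <- as.numeric(unname(p))
  }
  prior[c("control", "treatment")]
}

check_seed <- function(seed, required = FALSE) {
  if (is.null(seed)) {
    if (required) abort("A `seed` is required for Monte-Carlo computation.")
    return(NULL)
  }
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) || seed != floor(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed runs `code` on the ambient stream.
with_seed0 <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

# Derive `n` independent substream seeds from one master seed. Seeds are
# drawn below 2^31 so they remain representable as R integers.
derive_seeds <- function(seed, n) {
  with_seed0(seed, sample.int(.Machine$integer.max - 1L, n))
}

followup_weeks <- function(followup_days) followup_days / 7

# ---- success-boundary cache --------------------------------------------
#
# For a fixed control count (deaths_c out of analysed_c), prior and final
# threshold, the posterior probability P(p_T < p_C) is strictly decreasing
# in the number of treatment deaths. The largest treatment death count that
# still succeeds is therefore a well-defined critical value, found by
# bisection and memoised. Predictive-probability draws and whole-trial
# simulations classify imputed datasets by table lookup instead of
# re-evaluating the posterior probability per draw.

crit_cache_for <- function(prior, threshold) {
  key <- paste0("p", paste(signif(unlist(prior), 12), collapse = "_"),
                "_t", signif(threshold, 12))
  env <- the$crit[[key]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    the$crit[[key]] <- env
  }
  env
}

# Max treatment deaths (of analysed_t) for which the final success rule
# holds, or -1L if no count succeeds. `prior` is a normalised prior list.
crit_treatment_deaths <- function(deaths_c, analysed_c, analysed_t,
                                  prior, threshold, cache = NULL) {
  if (is.null(cache)) cache <- crit_cache_for(prior, threshold)
  key <- sprintf("%d_%d_%d", deaths_c, analysed_c, analysed_t)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  aC <- prior$control[1] + deaths_c
  bC <- prior$control[2] + analysed_c - deaths_c
  f <- function(dT) {
    psup_scalar(prior$treatment[1] + dT, prior$treatment[2] + analysed_t - dT, aC, bC)
  }
  # warm start: the boundary is non-decreasing in the control deaths and
  # moves by only a few per unit, so a cached neighbour is a tight lower
  # bound; step up geometrically from it, then bisect the bracket
  neighbour <- cache[[sprintf("%d_%d_%d", deaths_c - 1L, analysed_c, analysed_t)]]
  if (!is.null(neighbour) && neighbour >= 0L) {
    lo <- neighbour # f(lo) > threshold by monotonicity in deaths_c
    hi <- analysed_t
    step <- 4L
    while (lo + step < hi && f(lo + step) > threshold) {
      lo <- lo + step
      step <- step * 2L
    }
    if (lo + step >= hi && f(hi) > threshold) {
      cache[[key]] <- hi
      return(hi)
    }
    hi <- min(lo + step, hi)
  } else {
    if (f(0L) <= threshold) {
      cache[[key]] <- -1L
      return(-1L)
    }
    lo <- 0L
    hi <- analysed_t
    if (f(hi) > threshold) {
      cache[[key]] <- hi
      return(hi)
    }
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (f(mid) > threshold) lo <- mid else hi <- mid
  }
  cache[[key]] <- lo
  lo
}

# Vectorised classification of imputed final datasets: TRUE where the
# final success rule holds. All four count vectors have equal length.
classify_success <- function(deaths_c, analysed_c, deaths_t, analysed_t,
                             prior, threshold) {
  cache <- crit_cache_for(prior, threshold)
  base <- 1e5 # exact in doubles up to base^3 = 1e15 < 2^53
  key_num <- (as.numeric(analysed_t) * base + analysed_c) * base + deaths_c
  uniq <- unique(key_num)
  idx <- match(key_num, uniq)
  u_dc <- as.integer(uniq %% base)
  u_nc <- as.integer((uniq %/% base) %% base)
  u_nt <- as.integer(uniq %/% (base * base))
  crit <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    crit[i] <- crit_treatment_deaths(u_dc[i], u_nc[i], u_nt[i], prior, threshold, cache)
  }
  deaths_t <= crit[idx]
}
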