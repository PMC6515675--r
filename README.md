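# seqbayes

Bayesian sequential (adaptive) design for two-arm superiority trials with a
binary endpoint: conjugate beta-binomial inference, predictive-probability
stopping rules, operating-characteristics simulation, and virtual
re-execution of a design over a patient-level recruitment stream.

Phase III trials fix their sample size in advance and often learn too late
that a treatment is futile. A Bayesian sequential design adds scheduled
interim analyses at which the trial may stop early — for **futility** when
the posterior predictive probability of eventual success at the maximum
sample size, `P_max`, falls below a boundary `F_i`, or for **success** when
the predictive probability of success at the current sample size, `P_curr`,
exceeds a boundary `S_i`. The package is built around the critical-care
case study that motivated these tools (high-frequency oscillatory
ventilation vs conventional ventilation in ARDS, 30-day mortality,
N_max = 1006) and ships its six candidate designs, evaluation scenarios,
and observed interim counts. It is aimed at trial statisticians designing
or appraising sequential designs, and at anyone re-analysing a completed
trial under the rules it could have had.

## The model

Each arm's event probability gets an independent Beta prior (default
`Beta(1, 1)`); with `d` deaths among `n` complete outcomes the posterior is
`Beta(1 + d, 1 + n - d)`. The trial is successful when

```
P(p_T < p_C | data) > 0.975
```

computed exactly (closed-form finite sum for integer shapes, adaptive
quadrature otherwise). `P_curr` and `P_max` integrate over parameter
uncertainty — beta rates are drawn per imputation, then binomial outcomes
for in-transit and future patients (future patients thinned by the
anticipated 3% dropout) — with exact enumeration replacing Monte Carlo when
at most 20 patients are outstanding. The planned sample size comes from the
continuity-corrected (Fleiss) two-proportion formula; the final analysis
reports the posterior probability, death counts, and the relative risk with
the log-normal (Katz) 95% interval.

## Worked example

```r
library(seqbayes)

sample_size_two_proportions(0.45, 0.09, alpha = 0.05, power = 0.80, dropout = 0.03)
#> # A tibble: 1 × 4
#>   n_per_arm n_total n_uncorrected n_corrected
#>       <int>   <int>         <dbl>       <dbl>
#> 1       503    1006          466.        488.

prob_superiority(beta_posterior(93, 239), beta_posterior(96, 230))
#> P(p_T < p_C) = 0.733318  [closed_form]
```

503 patients per arm gives 80% power to detect a 9% absolute reduction
from a 45% control mortality at a two-sided 5% level with 3% dropout; the
posterior probability that the treatment arm (93/239 deaths) beats control
(96/230) is 0.73 — suggestive, far from the 0.975 bar.

Replay a two-look sequential design (interims at 335 and 670 recruits)
over the case study's observed recruitment stream, reconstructed as a
count-exact fixture:

```r
stream <- oscar_fixture("design3", seed = 2)
rx <- reexecute(stream, builtin_designs()$design3, n_draws = 10000, seed = 42)
rx
#> <reexecution> Design 3
#> Interim 1: continue (P(sup) = 0.8254, P_curr = -, P_max = 0.4162)
#> Interim 2: stop_futility (P(sup) = 0.6172, P_curr = 0.0000, P_max = 0.0156)
#>   futility_stop at n = 670; deaths 272; control 138/339, treatment 134/331
#>   final P(sup) = 0.5235, RR 0.99 (0.83, 1.19); accrual 121.8 weeks
```

At the first interim `P_max` (0.42) sits above `F_1 = 0.05`, so the trial
continues; by 670 recruits `P_max` has collapsed to ~0.013 < `F_2 = 0.1`
and the trial stops for futility — 336 patients short of the planned 1006,
with 272 deaths observed and a final relative risk of 0.99 (0.83, 1.19):
the same "no benefit" conclusion the full trial reached, sooner.
`tidy(rx)` and `glance(rx)` give the decision trail and final block as
tibbles; `autoplot(rx)` draws the trajectories against the boundaries.

Operating characteristics by simulation (here a small run; the harmful
scenario shows the futility rule doing its safety job):

```r
oc <- operating_characteristics(builtin_designs()$design5,
                                builtin_scenarios()$harmful,
                                n_sims = 500, seed = 1, n_draws = 2000)
oc
#> Operating characteristics: Design 5 under Treatment harmful: 45% vs 50% (500 simulated trials)
#>   mean n = 526 (sd 77), mean duration = 96 weeks
#>   stopped early: success 0.0000, futility 0.9940; overall successful 0.0000 (MC se 0.0000)
```

`run_simulate()`, `run_reexecute()` and `run_sample_size()` wrap these
into file-producing pipeline steps (CSV rendered to the conventional
digits, JSON twins at full precision, a manifest recording seeds and
sizes), and `inst/cli/seqbayes-cli.R` exposes them as shell subcommands.

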