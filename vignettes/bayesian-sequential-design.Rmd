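---
title: "Bayesian sequential two-arm designs: model, decision rules, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian sequential two-arm designs: model, decision rules, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbayes)
```

seqbayes implements a Bayesian sequential (adaptive) design for a two-arm
superiority trial with a binary endpoint observed after a fixed follow-up
window — the setting of a critical-care trial comparing high-frequency
oscillatory ventilation against conventional ventilation on 30-day
mortality, which supplies the built-in designs, scenarios and worked
examples. This vignette records the model, the decision rules, the
numerical choices, and what the simulation and fixture machinery does and
does not capture.

## The probability model

Each arm's event (death) probability gets an independent beta prior,

$$p_C \sim \mathrm{Beta}(\alpha_0, \beta_0), \qquad
  p_T \sim \mathrm{Beta}(\alpha_0, \beta_0),$$

with the uniform $\mathrm{Beta}(1,1)$ default: every event rate between 0
and 100% equally likely a priori. Outcomes are Bernoulli, so after $d$
deaths among $n$ complete outcomes the posterior is
$\mathrm{Beta}(\alpha_0 + d,\; \beta_0 + n - d)$ (`beta_posterior()`).
Priors are configurable per arm; nothing in the package requires them to be
integers, although the integer case unlocks an exact closed form below.

The trial is **successful** when the posterior probability that the
treatment has the lower event rate,

$$\pi = \Pr(p_T < p_C \mid \text{data}),$$

exceeds the final threshold (default 0.975, mirroring a one-sided 2.5%
level). The inequality is strict; the event $\{p_T = p_C\}$ has probability
zero, so this matters only for discrete numerical ties.

`prob_superiority()` evaluates $\pi$ three ways:

* **closed form** (the default when the control shape is an integer): the
  finite sum
  $\sum_{j=0}^{\alpha_C-1} B(\alpha_T+j, \beta_T+\beta_C) /
  \{(\beta_C+j)\, B(1+j,\beta_C)\, B(\alpha_T,\beta_T)\}$,
  evaluated in log space;
* **adaptive quadrature** of $\int f_C(x)\, F_T(x)\, dx$, which must reach
  an absolute tolerance (default $10^{-8}$) or it raises an error rather
  than returning a guess;
* **Monte Carlo** over paired beta draws, retained as an independent check
  and never used on a decision path.

The tests require the first two to agree to $10^{-8}$ and the complement
identity $\pi(A,B) + \pi(B,A) = 1$ to hold at the same tolerance.

## Interim decision rules

A `design_spec()` fixes the maximum sample size $N_{max}$, an interim
schedule by recruit count, per-interim boundaries, the final threshold and
the prior. At an interim with snapshot counts (randomised, complete,
deaths per arm):

* **P_max** — the posterior predictive probability that the trial would be
  successful at $N_{max}$: sample $(p_C, p_T)$ from the current posteriors,
  impute outcomes for the in-transit patients (enrolled, follow-up
  pending), allocate the $N_{max} - n$ future patients deterministically
  1:1 (odd remainder to control), thin the future patients by the
  anticipated dropout probability, and apply the final success rule to the
  completed dataset. Stop for **futility** when $P_{max} < F_i$.
* **P_curr** — the same construction with no future patients: the
  probability of success at the *current* sample size once everyone
  enrolled completes follow-up. Stop for **success** when $P_{curr} > S_i$,
  at interims where a success boundary exists.

Both probabilities integrate over parameter uncertainty (beta-binomial
predictive, not a plug-in binomial). Futility is evaluated **before**
success where both rules exist: the ordering is the package's choice — it
cannot matter except in boundary cases, and it prevents declaring success
for a trial that is predictively doomed at full size. Thresholds are strict
inequalities throughout.

Two deliberate asymmetries in dropout handling, both switchable:

* in-transit patients are **not** thinned by dropout (they are enrolled and
  being followed; `dropout_in_transit = TRUE` reverses this);
* future patients **are** thinned (default 3%), mirroring the dropout
  inflation in the planned sample size.

The 30-day follow-up lag means roughly `accrual_rate * 30/7` patients are
in transit at any interim (about 24 at 5.5/week).

## Numerical strategy

For fixed control counts the success rule is monotone in the treatment
death count, so there is a critical value: the largest number of treatment
deaths that still succeeds. Predictive draws are classified against
memoised critical values (found by bisection with a warm start from the
neighbouring control count) instead of re-evaluating $\pi$ per draw. The
cache is keyed by prior and threshold, so changing either cannot leak
stale boundaries. This makes a 10,000-draw predictive evaluation cost a
few hundred exact closed-form sums at first touch and almost nothing
afterwards, which is what keeps whole-design simulation tractable on one
CPU.

When at most 20 patients are outstanding (in transit plus future),
`predictive_prob_*` switches to **exact enumeration** over the per-arm
joint distribution of (future completers, added deaths) — binomial
thinning times the beta-binomial predictive — so small problems are exact
and the Monte-Carlo path can be validated against them (the tests compare
both against an independent per-sequence brute-force oracle).

Degenerate inputs are legal: zero unresolved patients collapses the
predictive probability to the 0/1 success indicator; a snapshot already at
$N_{max}$ behaves the same way.

## Sample size and the final summaries

`sample_size_two_proportions()` is the continuity-corrected
(Fleiss / Casagrande–Pike–Smith) two-proportion formula: the uncorrected
normal-approximation size $n'$ is corrected to
$n_{cc} = \tfrac{n'}{4}\bigl(1 + \sqrt{1 + 4/(n'd)}\bigr)^2$ with $d$ the
absolute risk difference, inflated for dropout by division, and ceilinged
per arm. At the built-in trial's inputs (45% control rate, 9% reduction,
two-sided $\alpha = 0.05$, 80% power, 3% dropout) it returns 503 per arm,
1006 in total, which is where the default $N_{max}$ comes from.

The final analysis reports $\pi$, the death counts, and the relative risk
with the standard log-normal (Katz) interval
$\exp\{\log \widehat{RR} \pm z \sqrt{1/d_T - 1/n_T + 1/d_C - 1/n_C}\}$.
The paper trail behind the built-in examples prints RRs to 2 decimals and
probabilities to 4; `run_reexecute()` renders the CSV views the same way
while the JSON twins keep full precision. Zero cells make the interval
undefined and raise an error; no silent continuity correction is applied.

## Virtual re-execution

`reexecute()` replays a design over an existing patient stream in
recruitment order. At each scheduled recruit count the snapshot contains
everyone randomised so far; a patient's outcome is visible only if they
were recruited at least one follow-up window before the trigger patient's
recruitment time and they are not a dropout. After a stop (or schedule
exhaustion) every randomised patient's follow-up is completed and the
final analysis run on all non-missing outcomes. Two conventions follow the
source setting: after a futility stop the trial is unsuccessful regardless
of where the final posterior lands, and accrual is assumed to cease
immediately, so the reported accrual duration is the trigger patient's
recruitment time. Missing outcomes are excluded from every analysis, never
imputed in a final analysis. Simultaneous recruits are ordered by patient
identifier — a stable, documented tie-break.

## Simulation and operating characteristics

`simulate_trial()` draws a stream (homogeneous Poisson accrual at the
scenario rate with no ramp-up, fair-coin 1:1 allocation, Bernoulli
outcomes, independent dropout decided at generation time), replays the
design, and summarises the trial. `operating_characteristics()` aggregates
replicates whose seeds are derived up front from one master seed, so
results are bit-reproducible and order-independent, and
`calibrate_thresholds()` reuses the same replicate seeds across a
threshold grid (common random numbers) so grid points differ only through
their boundaries.

Problem sizes: the package's own test suite runs the fixed design at
10,000–20,000 replicates (cheap: no interim machinery) and the sequential
design in a documented reduced-replicate mode — 2,000 trials with 2,000
imputation draws per interim look — with Monte-Carlo standard errors
reported alongside every proportion. Full 10,000/10,000 runs are a
command-line flag away and change only the Monte-Carlo error.

Two caveats worth stating plainly:

* **Accrual duration is not a target.** A homogeneous process at 5.5/week
  implies ~187 weeks for the fixed design including follow-up; the
  original study reported longer average durations, implying ramp-up or
  site-opening structure it does not specify. Mean duration is reported
  but should not be compared against the published duration column.
* **Interim-level behaviour is model-sensitive.** The aggregate operating
  characteristics (power, type I error, mean sample size, stopping
  proportions) reproduce the published values within Monte-Carlo
  tolerances, but how the stops distribute *across* interims depends on
  exactly how in-transit patients are imputed, which the source setting
  does not document. Our predictive probabilities are verified against
  exact enumeration; on the published interim snapshots they sit within
  the stated bands of the printed values, and a small systematic offset
  (ours slightly higher) is visible, consistent with a different
  imputation convention in the original software.

## The synthetic-data generator and fixtures

`generate_stream()` emulates exactly what the analysis model assumes:
Poisson accrual, coin-flip allocation, Bernoulli outcomes, independent
missingness. It deliberately does **not** emulate site effects, covariates,
calendar seasonality, accrual ramp-up, or informative dropout. Passing
tests therefore demonstrate that the decision machinery is correct under
its own assumptions — not that those assumptions describe any real trial.

`generate_fixture()` solves the inverse problem: given pinned per-arm
counts at interim triggers (and final denominators), it lays out a stream
whose snapshots reproduce them exactly. Completeness is controlled purely
by recruit-time placement — patients required to be complete at a trigger
are recruited at least one follow-up window before the trigger patient,
in-transit patients inside the trailing window — and the within-window
recruit times are evenly spaced, not Poisson: fixtures pin counts, not
accrual realism. Dropouts are placed as late as the block structure
allows. Infeasible constraint sets (non-monotone counts, windows shorter
than the follow-up lag, patients that would have to be complete at their
own randomisation) fail with the first violated inequality named.
`verify_fixture()` recounts every pinned snapshot independently, and the
built-in `oscar_counts()` / `oscar_fixture()` pairs reconstruct the
observed interim trails of the case-study trial for all built-in
sequential designs.

## Known limitations

* Binary endpoint with a fixed follow-up window only; no time-to-event or
  longitudinal modelling, and no covariate adjustment.
* One-sided superiority framing: "harm" is caught by the futility rule,
  not by a dedicated harm boundary.
* The published posterior probabilities for some interim cells differ from
  the exact beta-binomial values by up to ~0.03 (the original analyses
  were sampling-based); the package computes the exact values and makes no
  attempt to reproduce sampling noise.
* Estimates after early stopping are reported as-is; no bias correction
  for sequential stopping is applied.
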