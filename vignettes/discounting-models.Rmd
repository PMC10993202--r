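---
title: "Modelling delay discounting with discountr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delay discounting with discountr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The task and the data

`discountr` models behaviour in an adaptive intertemporal-choice task. On
each trial a participant chooses between an immediate reward and a larger
reward of 40 units delivered after one of six delays (2 days, 2 weeks, 1, 3
or 6 months, or 1 year; months are treated as 30 days, the year as 365 —
the simplest calendar convention, configurable in `staircase_config()`).
The immediate offer is titrated by an amount-adjustment staircase: it starts
at 20 units and, after each choice, moves by 10, 5, 2.5 and finally 1 unit —
up when the delayed reward was chosen, down otherwise. Five choices per
delay form a block, six blocks (one per delay, randomly ordered) form a run,
and each condition (food, money) is run twice, runs alternating
food–money–food–money. A participant-condition therefore contributes
2 × 6 × 5 = 60 binary choices.

The package works on tidy trial tables (one row per choice) with the columns
`participant_id`, `condition`, `run`, `block`, `trial`, `delay_days`,
`amount_immediate`, `amount_delayed`, `choice` and optionally `rt_s`.

# Choice models

Eight models produce a decision value (DV) for choosing the delayed option.

**Option-based subjective-value models** discount each option independently
and take `DV = SV(delayed) − SV(immediate)` (an immediate option keeps its
face value):

* exponential: $SV = A e^{-kD}$
* exponential with scaling: $SV = A e^{-(kD)^s}$
* hyperbolic: $SV = A/(1+kD)$
* hyperbolic with delay scaling: $SV = A/(1+kD^s)$
* hyperbolic with denominator scaling: $SV = A/(1+kD)^s$

`k` (per day) measures impulsivity — how steeply value decays with delay;
`s` (dimensionless) modulates delay sensitivity, with $s=1$ reducing each
scaled model exactly to its unscaled form and $s<1$ compressing long delays.

**Attribute-wise heuristic models** compare the options' attributes
directly. With immediate amount $x_1$ (delay $t_1 = 0$) and delayed amount
$x_2$ at delay $t_2$:

* ITCH: $\beta_{xA}(x_2-x_1) + \beta_{xR}\frac{x_2-x_1}{(x_2+x_1)/2} +
  \beta_{tA}(t_2-t_1) + \beta_{tR}\frac{t_2-t_1}{(t_2+t_1)/2}$. The relative
  terms are divided by the two-option mean, the canonical form of the model.
* DRIFT: $\beta_{xA}z(x_2-x_1) + \beta_{xR}z(\frac{x_2-x_1}{x_1}) +
  \beta_{tA}z(t_2-t_1) + \beta_{xt}z\big((x_2/x_1)^{1/(t_2-t_1)}-1\big)$,
  the last factor being the implied per-period growth rate.
* TRADE: with $v(x) = \log(1+\mathrm{scaling2}\cdot x)/\mathrm{scaling2}$
  and $w(t) = \log(1+\mathrm{scaling3}\cdot t)/\mathrm{scaling3}$,
  $DV = (v(x_2)-v(x_1)) - \mathrm{scaling1}\,(w(t_2)-w(t_1))$.

Every model shares the lapse-limited inverse-logit choice rule
$p(\text{delayed}) = (1-2\epsilon)\,\mathrm{logit}^{-1}(DV) + \epsilon$,
which bounds predictions in $[\epsilon, 1-\epsilon]$ and keeps the Bernoulli
log likelihood finite for any finite or infinite DV whenever $\epsilon > 0$.

## Design choices in the heuristic models

Three points of the heuristic-model definitions are genuinely open, and the
package resolves them as follows.

* **DRIFT's standardizer $z$.** The model's regression-style origin implies
  standardized factors, but no canonical definition of the standardization
  scope exists. `discountr` standardizes each factor within a
  participant-condition's trials (centre, divide by SD), falling back to a
  unit SD when a factor has zero spread — so a degenerate factor contributes
  0 rather than breaking the fit. The standardizer is injectable
  (`standardizer` argument), and `identity` gives raw factors.
* **TRADE's sign.** The delay term enters negatively
  ($-\,\mathrm{scaling1}(w(t_2)-w(t_1))$), so longer delays penalize the
  delayed option; the opposite sign would make delay attractive and
  contradict discounting. `scaling2` and `scaling3` must be positive (they
  sit inside logarithms); `scaling1` may be zero, switching delay
  sensitivity off.
* **Numerical stability.** The inverse logit is computed by `plogis`
  (branching internally on the sign of its argument) and the result is
  clamped to the lapse band to absorb last-bit float excursions; subjective
  values underflow to exactly 0 only where $e^{-(kD)^s}$ is smaller than the
  smallest double, far outside the fitted range.

# Hierarchical estimation

`fit_dd()` fits one model to one condition. The hierarchy places independent
uniform hyperpriors on each parameter's population mean and SD
(see `dd_priors()`): `k`'s mean ranges over $[e^{-10}, e^{-2}]$ with SD in
$[0.01, 3]$ and starting point $(e^{-2.5}, 1)$; `s`'s mean over $(0, 4]$;
all heuristic weights and scalers over $[-1, 1]$ with SD in $(0, 1]$; and
the lapse over $(0, 0.2]$. Participant-level parameters are normal around
the population mean, truncated to each parameter's support: $k, s > 0$,
lapse in $(0, 0.2)$, TRADE scalers positive, regression weights unbounded.
The posterior is never cut off at the upper end of plausible `k` values, a
requirement for unbiased population estimates; the left truncation at 0 is a
package decision, since negative discount rates are undefined in the SV
models.

Sampling is done with JAGS (adaptive Gibbs/slice sampling via `rjags`), with
chain starting values taken from the prior table's starting points and
jittered per chain, and per-chain RNG seeds derived deterministically from
the fit seed, so identical seeds give bit-identical draws. Warm-up is split
between sampler adaptation and burn-in.

Two sampler choices matter for mixing; neither changes the posterior.
First, the hierarchy uses a *mixed parameterization*: the discount rate `k`
drives every choice directly and is strongly informed per participant, so
its participant-level values are sampled centered; the modulators (`s`, the
lapse, the heuristic weights and scalers) are weakly informed and funnel
when the population SD collapses toward zero, so they are sampled
non-centered — a standard-normal deviate per participant, truncated so that
`mu + sd * deviate` respects the parameter's support. Second, because a
scalar slice-sampling iteration carries far less information than a
gradient-based one, retained draws are thinned (keep every 10th by default,
`thin` in `dd_fit_config()`); `draws` always counts retained draws, so the
warm-up length and the number of collected samples keep their documented
meanings.

Full-scale defaults follow the documented analysis settings — 60,000
warm-up iterations and 1,500 retained draws — while the package's
reduced-scale settings (2,000 warm-up, 500 retained draws, 4 chains,
thinning 10) are adequate for clean synthetic cohorts of the sizes used in
the tests; convergence is always checked, never assumed. Every fit
monitors all population- and participant-level parameters plus the per-trial
pointwise log likelihood, and computes rank-normalized split-Rhat per
parameter, flagging values above 1.1. A parameter whose draws are all
identical has no between/within-chain variance to compare and is reported as
Rhat 1.

# Model comparison, recovery and contrasts

**WAIC** is computed on the negative-log scale from the stored pointwise log
likelihood: per observation, `lppd` is the log of the mean posterior
likelihood (via a log-sum-exp) and the penalty is the posterior variance of
the log likelihood; the criterion is the negated sum, its SE
$\sqrt{N}\,\mathrm{sd}$ of the pointwise contributions. `compare_models()`
ranks models ascending and flags the winner significantly better than the
runner-up when the WAIC difference exceeds twice the SE of the *paired*
pointwise difference — a package operationalization, standard
information-criterion practice. A deviance-scale WAIC is simply twice the
reported value.

**Parameter recovery** (`parameter_recovery()`) simulates a cohort from
specified participant parameters, refits, and correlates posterior means
with the generating values. On clean synthetic data with the generating and
fitted model matched, recovery of `k` is expected to be strong; the
empirical benchmark of r = 0.66 on a real cohort acts as a lower bound in
the acceptance checks rather than a target, because real estimates carry
noise the generator does not emulate.

**Condition contrasts** (`condition_contrast()`) are computed on
population-level `Mu` draws — the only level at which the delta has a proper
posterior — as the per-draw difference between two fits, summarised by its
mean and 95% HDI (shortest contiguous window of sorted draws containing 95%
of them). An HDI touching zero from one side still counts as excluding zero
(steeper discounting at the boundary), but a degenerate all-zero delta does
not. A participant-level aggregate is available by contrasting
`participant_estimates()` by hand.

# The synthetic-data generator

`simulate_cohort()` *is* the study conditions: fixed delayed reward of 40
units, initial offer 20, steps 10/5/2.5/1, six delays, five choices per
block, two runs per condition in food–money alternation. Participant
parameters are drawn from truncated normal population distributions matching
the inference module's supports. Defaults emulate a winning-model cohort:
population `k` mean 0.05 day⁻¹ and SD 0.02 (a mid-range of empirically
plausible discount rates for these delays), `s = 1`, lapse 0.05 — values a
behavioural study of this design would consider typical. Choices are drawn
Bernoulli from the model's choice probability; a deterministic
probability-thresholded responder is available for calibration checks, where
the titrated indifference point provably converges to within the final step
(1 unit) of the generative subjective value.

What the generator does **not** emulate: reaction times and attention
lapses beyond the constant lapse rate, within-session drift (fatigue,
satiety), block-order effects, and the possibility that no fitted model is
the true data-generating process. Passing recovery and comparison tests on
synthetic cohorts therefore shows the pipeline is consistent — it finds back
what generated the data — not that real behaviour satisfies any one model.

The indifference point plotted by `plot_indifference_points()` is the
hypothetical sixth offer of a block (the final offer adjusted once more by
the final 1-unit step in the direction of the last choice), the standard
titration estimate; other conventions (e.g. the mean of the last two
offers) differ from it by at most the final step.

Quality control mirrors the behavioural exclusion rules: participants
choosing the same option in strictly more than 90% of their trials (pooled
across conditions), or — when reaction times are present — responding slower
than 12 s on more than half of their trials, are excluded with a reported
reason.

# Reduced-scale test design

The validation suites run at sizes chosen to exercise the statistical
properties in minutes, as the package's reduced-scale defaults: convergence
and recovery checks use cohorts of 10–20 participants at 2,000 warm-up /
500 draws / 4 chains with the default thinning; the model-recovery matrix
uses 10 replicates of 8-participant cohorts (generators: exponential with
`k = 0.05`; scaled exponential with `s = 0.6`, distinguishable from its
unscaled special case; hyperbolic with `k = 0.05`) at 800 / 300 / 2 chains;
the contrast sign-recovery uses 20 participants with population `k` 0.06 vs
0.03 (delta 0.03) or a null delta, 5 replicates per scenario at
1,000 / 400 / 2 chains. The replicate suites assert rank and sign outcomes
rather than convergence diagnostics, so they run unthinned. These sizes
were fixed once from a sampler-throughput pilot and are not tuned to
outcomes.

# Known limitations

* The sampler is JAGS's adaptive Gibbs/slice scheme, not a gradient-based
  one; for these models it mixes well at far fewer iterations than the
  full-scale warm-up default, but heavily correlated heuristic-model
  posteriors (e.g. ITCH weights on collinear factors) can mix slowly.
* Uniform hyperpriors bound the population mean of `k` at $e^{-2} \approx
  0.135$; cohorts discounting more steeply than that are pushed against the
  prior edge (participant-level values remain free).
* DRIFT's standardization makes its decision values dataset-relative:
  refitting on a subset changes the factors, which is inherent to the
  model's definition, not to the implementation.
* The heuristic models are fitted with the same lapse-limited rule as the SV
  models; no reaction-time or drift-diffusion information is used.
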