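---
title: "Models, designs, and the recovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, designs, and the recovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcmodels)
```

## The problem

Inter-temporal choice models are routinely used as *measurement* models:
a discount-rate parameter fitted to someone's choices between a
smaller-sooner (SS) and a larger-later (LL) monetary option is read as an
index of their impatience. That reading is only justified if the parameter
can actually be estimated from the kind of data being collected. This
package implements eleven prominent choice models together with three
standard choice-set designs, a synthetic-participant generator, Bayesian
estimation, and two reliability analyses — parameter recovery (fit the
model to data simulated from known values and see whether the values come
back) and parameter consistency (fit the model separately to different item
subsets answered by the same person and correlate the estimates).

## Models

Eight models value each option separately. Seven are multiplicative
discounted-utility forms, `V = x * D(t)` with `0 <= D <= 1`:

| model | discount factor `D(t)` | parameters |
|---|---|---|
| exponential | `exp(-k t)` | `k` |
| hyperbolic | `1 / (1 + k t)` | `k` |
| double exponential | `w exp(-b t) + (1 - w) exp(-d t)` | `b, d, w` |
| generalized hyperbolic | `1 / (1 + k t^s)` | `k, s` |
| hyperboloid | `1 / (1 + k t)^s` | `k, s` |
| generalized hyperbola | `1 / (1 + a t)^(b/a)` | `a, b` |
| constant sensitivity | `exp(-(a t)^b)` | `a, b` |

The additive-utility model is `V = x^alpha - lambda * t^beta`; the amount
lost to delay does not scale with the amount at stake, which is what lets
it produce the magnitude effect. All eight use the logistic choice rule
`p(LL) = L(sigma * (V_LL - V_SS))`, with `sigma > 0` controlling choice
determinism.

Three models compare attributes across options instead of valuing options:

* **Proportional difference** computes
  `d = (max(x) - min(x)) / max(x) - (max(t) - min(t)) / max(t)` and chooses
  through a probit rule `p(LL) = Phi(sigma * (d - delta))`; positive
  `delta` biases toward the sooner option. The likelihood is parameterized
  so that larger `sigma` means more deterministic choices. Note that with
  an immediate SS option (`t_ss = 0`) the delay term is identically 1, so
  the model is blind to the LL delay on such items.
* **ITCH** is a logistic regression on the absolute and relative amount and
  delay differences, with the *mean* of the two options' attribute values
  as the reference point for the relative terms.
* The **trade-off model** maps amounts and delays through log utility /
  log delay-weighting functions, applies a sub/super-additivity weighting
  to the delay difference, and chooses by the ratio rule
  `p(LL) = Qv^(1/eps) / (Qv^(1/eps) + Qw^(1/eps))`. Its loss branch (for
  negative payoffs) is out of scope here since all designs use gains.

Reduction identities (e.g. generalized hyperbolic at `s = 1` is the
hyperbolic model; constant sensitivity at `b = 1` is exponential) are
enforced by property tests to floating tolerance.

### Numerical choices

Choice probabilities are never formed by naive exponentiation:
log-probabilities go through `plogis(z, log.p = TRUE)` /
`pnorm(z, log.p = TRUE)` and the trade-off rule is evaluated as a logistic
in `(log Qv - log Qw) / eps`, so large `sigma` or small `eps` cannot
overflow and likelihood terms of exactly 0/1 cannot arise from rounding.
Degenerate items (non-ordered amounts or delays) are rejected at
construction, which in turn guarantees `Qv, Qw > 0` for the trade-off
model.

Every parameter lives on a declared support and has a transform to an
unconstrained scale (log for positive parameters, logit for the
double-exponential weight, `log(theta - 1)` for the trade-off
super-additivity parameter, identity for unconstrained weights). The
double-exponential model is identified by requiring the impatient rate to
be at least the patient one (`b >= d`), implemented by sampling
`log(b - d)`; without this the model is symmetric under
`(b, w) <-> (d, 1 - w)` relabelling.

## Designs

* `kirby_mcq()` — the canonical 27-item monetary choice questionnaire:
  immediate SS rewards of $11–$80 against delayed $25–$85 at 7–186 days,
  three magnitude tiers of 9 items. Delays in days.
* `factorial_grid()` — 380 items crossing $120–$500 (in $20 steps) at
  2–38 months (in 2-month steps) against $100 now. Delays in months.
* `tailored_sets()` — 3 × 100 items per participant, each subset built to
  elicit one effect: delay-duration (`t_ll = 2 t_ss`), common-difference
  (`t_ll = t_ss + 30` days), magnitude (`x_ll = 2 x_ss`), with short delays
  and small amounts spanning 2–40 (days / dollars).

Time units are design-native and recorded in every dataset; rate-like
parameters are therefore unit-dependent, and the package never converts
units silently.

For the tailored design the original interactive adjustment staircase is
not reproduced (its update and stopping rules are not available); instead
the free attribute of each item is placed at the generating model's
indifference point (found by root-solving the decision score) and
multiplied by jitter drawn uniformly in `[0.7, 1.3]`. This surrogate keeps
the generator self-contained while reproducing the design's signature
property — choice rates that sit near, but not at, indifference and can
polarize for mismatched models. The jittered amounts are clamped to
`[1.05, 4] * x_ss` and tailored delays to `(t_ss, 200]` days, keeping all
items inside the ranges the design family uses.

## Synthetic populations

`population_spec()` / `sample_population()` draw participant-level
parameters from independent normals on the unconstrained scale — e.g. the
hyperbolic defaults are `log k ~ Normal(log 0.1, 1)` and
`log sigma ~ Normal(log 0.1, 1)` in design-native units. Defaults for every
model are declared in the source and overridable; they were chosen once to
give plausible discounting and moderately noisy responding under these
designs. Seeding uses a master seed split into per-participant substreams,
so any participant's draw (and any recovery cell) regenerates
independently and bit-identically.

What the generator deliberately does not emulate: demographic covariates,
response times, within-person drift over time, item-order effects, and the
exact population shape of any real sample. Passing recovery tests on these
synthetic populations therefore demonstrates properties of the
*model/design pair*, not of any particular empirical dataset.

## Estimation

Two modes share one likelihood implementation (cross-checked against
`dataset_loglik()` by tests):

* **MAP + Laplace** (`method = "map"`): BFGS posterior-mode search on the
  unconstrained scale with a normal approximation from the inverse
  Hessian. Deterministic given the data, and fast enough to power the
  recovery pipeline (a 380-item two-parameter fit takes well under a
  second).
* **Adaptive Metropolis MCMC** (`method = "mcmc"`): random-walk Metropolis
  whose proposal scale and covariance adapt during warmup, initialised at
  the MAP solution. Defaults are 4 chains × 2000 warmup × 2000 retained
  draws (8000 retained). Convergence is assessed by split-Rhat (≤ 1.01)
  and effective sample size (≥ 400); fits failing the thresholds are
  returned flagged, never silently accepted or dropped, and downstream
  recovery summaries report the flag rate.

Priors are proper independent normals on the unconstrained scale — the
population defaults with doubled standard deviations — so that weakly
informative data (27 items, or an all-one response column) yield wide
intervals rather than estimation failures.

`fit_hierarchical()` models unconstrained participant parameters as
`theta_i ~ Normal(mu, tau^2)` per parameter, with conjugate
`Normal`/`Inverse-Gamma(2, 0.5)` hyperpriors, alternating per-participant
Metropolis block updates with exact Gibbs draws of `mu` and `tau`.

`waic()` implements the deviance-scale widely applicable information
criterion from the pointwise log-likelihood matrix; `compare_models()`
ranks models by it.

## Recovery and consistency

`run_recovery_cell()` simulates, per generating parameter combination and
replicate, one response set on the cell's items, refits the model
independently, and records posterior medians and central 95% intervals.
`summarize_recovery()` then averages the per-replicate medians and interval
bounds per combination (the averaged 95% interval is the headline recovery
measure) and reports, per parameter, the correlation between generating
and recovered values. Where the interval construction was genuinely open,
the package computes one correlation per replicate index and reports the
2.5/97.5 percentile range; the point value correlates generating values
with replicate-averaged medians. Correlations default to the unconstrained
scale, where parameters spanning orders of magnitude are comparable; this
is configurable. Generating combinations are sampled *jointly* — one
participant (and, for hierarchical sources, one retained draw) per
combination — preserving dependencies between parameters.

`fit_by_subset()` and `cross_subset_correlations()` implement the
consistency analysis: fit each participant separately per effect subset
and interval-estimate the across-participant correlation of each
parameter between subset pairs. With MCMC fits the interval is draw-wise
(correlating participants' values at each retained draw index — a genuine
credible interval); with MAP fits it is a nonparametric bootstrap over
participants. An interval excluding zero flags the correlation as
credible. These two constructions are package design choices where the
original analysis left the mechanism unstated.

At full scale the recovery plan crosses 3 designs × 11 models × 100
combinations × 100 replicates (10000 response sets per cell, 330000
total); `plan_counts()` enumerates this without fitting. The package's own
test suite exercises the pipeline at reduced sizes chosen to keep the
whole suite in the minutes range while leaving the statistical checks
well-powered: 40–50 combinations × 1 replicate for recovery correlations,
200 replicate fits for interval-coverage calibration, 8–12 participants
for hierarchical checks.

## Known limitations

* The MAP/Laplace mode relies on a quadratic posterior approximation; for
  weakly identified models (double exponential, trade-off) its intervals
  are approximate and the MCMC mode should be preferred.
* The random-walk sampler is adequate for the ≤ 6-parameter posteriors
  here but mixes more slowly than gradient-based samplers; effective
  sample sizes per iteration are correspondingly lower.
* The tailored-design surrogate is not the original adjustment staircase;
  analyses of tailoring-specific artefacts should treat it as a
  qualitative stand-in (it is labelled as such in the documentation).
* Population defaults are declared, not estimated from any dataset;
  replication against real data should override them and use hierarchical
  posterior draws as the generating source for recovery
  (`sample_generating_combos()` accepts either source).
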