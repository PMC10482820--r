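# itcmodels

Simulation, Bayesian estimation, and reliability analysis for models of
inter-temporal choice (delay discounting).

## What this is for

Inter-temporal choice models are widely used as measurement instruments:
a discount rate `k` fitted to someone's choices between a smaller-sooner
(SS) and a larger-later (LL) reward is interpreted as their level of
impatience. Whether that interpretation is warranted depends on whether
the parameter can be reliably estimated from the item set actually used —
which varies dramatically across models and designs. This package gives
researchers the tools to check, for any of eleven prominent models and any
choice set:

* **parameter recovery** — simulate responses from known parameter values,
  refit, and measure how well the values come back;
* **parameter consistency** — fit the same participants separately on
  different item subsets and correlate the estimates;
* **descriptive adequacy** — compare models on a dataset by WAIC.

## Models

Eleven models are implemented as value / choice-probability /
log-likelihood functions with seeded simulation. Eight value options
separately — exponential `V = x e^{-kt}`, hyperbolic `V = x/(1+kt)`,
double exponential, generalized hyperbolic `x/(1+kt^s)`, hyperboloid
`x/(1+kt)^s`, generalized hyperbola `x/(1+αt)^{β/α}`, constant sensitivity
`x e^{-(αt)^β}`, and additive utility `x^α − λt^β` — and choose by the
logistic rule `p(LL) = L(σ(V_LL − V_SS))`. Three compare attributes across
options: the proportional-difference model (probit rule on its difference
statistic `d`), the inter-temporal choice heuristic (ITCH; logistic in
absolute and mean-referenced relative attribute differences), and the
trade-off model (ratio rule `Q_v^{1/ε}/(Q_v^{1/ε}+Q_w^{1/ε})` on
log-utility and weighted log-delay differences).

Three standard designs are generated in code: the 27-item Kirby monetary
choice questionnaire (3 magnitude tiers × 9 items, immediate SS options),
a 380-item factorial grid ($120–$500 by $20 × 2–38 months by 2, against
$100 now), and participant-tailored 3 × 100-item effect subsets
(delay-duration, common-difference, magnitude).

Estimation is Bayesian on an unconstrained parameter scale, either by a
deterministic MAP + Laplace approximation (fast; default in the recovery
pipeline) or by adaptive-Metropolis MCMC (4 chains × 2000 warmup × 2000
retained draws by default) with split-Rhat and effective-sample-size
diagnostics, plus hierarchical fitting with conjugate population updates.

## Worked example

Sample a small synthetic population of hyperbolic discounters, generate
their responses on the factorial grid, fit one participant, compare three
models, and run a miniature recovery:

```r
library(itcmodels)

pop     <- population_spec("hyperbolic", n_participants = 5, seed = 11)
truth   <- sample_population(pop)
round(truth$k, 4)
#> [1] 0.1029 0.1588 0.1582 0.8958 0.0833

dataset <- generate_dataset(truth, factorial_grid(), seed = 12)  # 1900 rows
p1      <- dataset[dataset$participant_id == "p001", ]

posterior_summary(fit_individual("hyperbolic", p1, method = "map"))
#>   parameter median     lo     hi median_unc lo_unc hi_unc
#> 1         k 0.1058 0.0975 0.1149      -2.25  -2.33  -2.16
#> 2     sigma 0.0564 0.0459 0.0693      -2.88  -3.08  -2.67
```

Participant 1's true `k` of 0.103 (per month) is recovered as 0.106 with a
tight 95% interval; `sigma` is the inverse-noise of the logistic choice
rule. WAIC correctly prefers the generating model:

```r
compare_models(p1, c("hyperbolic", "exponential", "constant_sensitivity"),
               sampler = sampler_config(n_chains = 2, n_warmup = 200, n_draws = 500))
#>                  model   waic     se p_waic rank
#> 1           hyperbolic 266.17 23.858 2.3264    1
#> 2 constant_sensitivity 269.40 23.688 3.2581    2
#> 3          exponential 281.64 23.479 2.3391    3
```

A recovery cell: 20 generating combinations × 2 replicate response sets,
each refit independently; correlations are between generating and
recovered values on the log scale:

```r
combos <- sample_generating_combos(truth, 20, seed = 13)
raw    <- run_recovery_cell("hyperbolic", factorial_grid(), combos,
                            n_replicates = 2, method = "map", seed = 14)
summarize_recovery(raw)
#> <itc_recovery_summary> hyperbolic: 20 combos x 2 replicates (0.0% flagged)
#>   parameter        r     ci_lo     ci_hi
#> 1         k 0.998726 0.9974877 0.9987411
#> 2     sigma 0.984643 0.9612084 0.9718432
```

Both hyperbolic parameters recover almost perfectly on the 380-item grid
(the interval is the percentile range of per-replicate correlations; the
point value correlates replicate-averaged medians, so it can exceed the
interval). `plot_recovery()` draws the generating-versus-recovered scatter
with averaged 95% error bars and the identity line. On the 27-item
questionnaire the same exercise gives visibly lower correlations — the
package's test suite checks exactly that design dependence.

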