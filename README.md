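# barbedend

Kinetic analysis of multicomponent regulation at actin filament barbed
ends — formin (F), capping protein (CP, C) and twinfilin (T) competing
for, and cooperating at, the same filament end.

## What it is for

When a processive formin and capping protein occupy a barbed end
simultaneously, the resulting **decision complex** (`BFC`) resolves by one
of two routes: CP departs and elongation resumes (`BFC → BF + C`), or
formin departs and the filament is lost (`BFC → BC + F`). Twinfilin
visits the complex transiently and biases this decision. Experiments of
this kind are quantified from cohorts of filaments watched in TIRF
microscopy: survival fractions of a bound state over time, outcome counts
for each route, and single-molecule dwell times and visit counts. This
package provides that entire analysis chain, plus a synthetic-data
generator that emulates the statistical structure of the microscopy so
every estimator can be validated against known ground truth.

The core model is a continuous-time Markov chain over eight occupancy
states (`B`, `BF`, `BC`, `BCT`, `BFC`, `BFCT`, and two absorbing
observation states). For the two-route decision complex the occupancy has
the closed form

```
BFC(t)/BFC0 = exp(-(k'_C + k'_F) t)
BF(t)/BFC0  = k'_C/(k'_C + k'_F) * (1 - exp(-(k'_C + k'_F) t))
BC(t)/BFC0  = k'_F/(k'_C + k'_F) * (1 - exp(-(k'_C + k'_F) t))
```

so the total dissociation rate `k_BFC = k'_C + k'_F` is fit from the
survival curve and split between the two routes by the observed outcome
counts, `N_BF / N_BC = k'_C / k'_F`. Uncertainties use a parametric
bootstrap (simulated replicate cohorts refit at the estimated rate; 65%
percentile interval and sd). Twinfilin's action is modeled mechanistically:
transient visits (states `BCT`, `BFCT`) with exponential residence, each
visit removing CP with a fixed per-visit probability — so visit counts to
uncapping are geometric and the probability is estimated as the
reciprocal mean visit count.

## Worked example

Simulate a control decision-complex cohort (no twinfilin) at the default
rates — mean complex lifetime 149 s, routes split 30:42 toward BC — and
recover the kinetics:

```r
library(barbedend)
rates <- default_rates()
sim   <- simulate_cohort(rates, 1000, "BFC", window = 1500, seed = 42)
fit   <- fit_single_exponential(survival_curve(sim$events))
fit   <- bootstrap_rate_ci(fit$rate, n = 1000, reps = 1000,
                           window = 1500, seed = 43)
fit
#> Dissociation rate: 0.006864 s^-1 (n = 1000, ls fit)
#>   65% CI [0.00667, 0.007106] s^-1, bootstrap sd 0.0002428
decompose_routes(sim$events)
#> BFC dissociation: k_BFC = 0.006864 s^-1
#>   to BF (CP left):     k'_C = 0.002807 s^-1  (N_BF = 409, 40.9%)
#>   to BC (formin left): k'_F = 0.004057 s^-1  (N_BC = 591, 59.1%)
```

The fitted `k_BFC` of 0.0069 s⁻¹ corresponds to a mean lifetime of
146 s (truth: 149 s), and the route split (40.9% to BF) recovers the
generating 30/72 ≈ 41.7% within binomial error. Dwell-time analysis works
on rendered traces:

```r
r  <- rate_set(k_minus_T = 1/1.9, p_uncap_BCT = 1/30.9, k_on_T = 1, conc_T = 0.05)
tr <- simulate_trajectory(r, "BC", t_max = 3000, seed = 7)
iv <- binarize_trace(render_trace(tr, "twinfilin", 0.2), threshold = 0.5)
dwell_summary(iv)
```

A thin command-line front end over the same functions lives at
`inst/cli/bek.R` (subcommands `run`, `simulate`, `fit-survival`,
`decompose`, `dwell`, `uncap-visits`, `bootstrap`).

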