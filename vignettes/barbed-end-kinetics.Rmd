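---
title: "Modeling multicomponent barbed-end regulation: methods and design notes"
author: "barbedend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multicomponent barbed-end regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barbedend)
```

## The biological problem

The barbed (fast-growing) end of an actin filament is a small battleground:
formin (F) attaches processively and accelerates elongation, capping
protein (CP, C) arrests it, and twinfilin (T) destabilizes CP. When formin
and CP occupy the same end, the resulting "decision complex" (BFC) can
resolve in two ways — CP leaves and elongation resumes (BFC → BF + C), or
formin leaves and the filament is lost (BFC → BC + F). Twinfilin visits
the complex transiently and strongly biases that decision. This package
implements the kinetic machinery needed to quantify such experiments:
a stochastic state model of barbed-end occupancy, survival-curve fitting,
a two-route rate decomposition, bootstrap uncertainty, and single-molecule
dwell/visit statistics — together with a synthetic-data generator that
stands in for microscopy, since the quantities of interest are all defined
on extracted event tables and 1-D intensity traces.

## The state model

Eight states (`BARBED_STATES`) describe which proteins occupy the end:
`B`, `BF`, `BC`, `BCT`, `BFC`, `BFCT`, plus two absorbing observation
states, `DETACHED` (the filament leaves the field of view when formin
releases it) and `UNCAPPED_DEPOL` (a twinfilin-uncapped end
depolymerizing). Transitions form a continuous-time Markov chain whose
propensities are assembled by `build_transition_table()` from a
`rate_set`:

* first-order exits: `k_minus_F` (BF → B), `k_minus_C` (spontaneous
  uncapping BC → B), `kprime_minus_C` and `kprime_minus_F` (the two BFC
  routes), `k_minus_T` / `k_minus_T_BFCT` (twinfilin departures);
* bimolecular associations `k_on_C`, `k_on_T` (per uM per s), multiplied
  by the constant phase concentrations `conc_C`, `conc_T` at table-build
  time (pseudo-first-order), because concentrations are held fixed within
  an experimental phase;
* per-visit uncapping probabilities: a twinfilin departure from `BCT`
  removes CP with probability `p_uncap_BCT`; from `BFCT` it removes CP
  (and itself, in a single event) with probability `p_uncap_BFCT`,
  leaving `BF`. The simultaneous-departure convention reflects the
  single-molecule observation that CP and twinfilin leave the trimeric
  complex together, leaving formin behind.

Two open modeling choices were resolved conservatively. Formin loss from
the trimeric complex (BFCT → BCT) has never been observed, so its rate
`k_minus_F_BFCT` defaults to 0 but is exposed as an ordinary parameter.
CP arrival at a twinfilin-occupied formin end is not modeled at all, since
simultaneous arrivals have not been observed.

With `conc_T = 0` the BFC exits reduce exactly to the two-route model,
whose occupancy has the closed form implemented in `bfc_survival()` and
`occupancy_fractions()`:

$$\mathrm{BFC}(t) = e^{-(k'_{-C}+k'_{-F})t},\qquad
\mathrm{BF}(t) = \frac{k'_{-C}}{k'_{-C}+k'_{-F}}\,(1-e^{-(k'_{-C}+k'_{-F})t}),$$

and symmetrically for BC(t). The three fractions sum to one identically;
the package enforces this to 1e-12 and the asymptotic split equals
`route_fraction_bf()`. Under twinfilin the fitted rates are *observed*
rate constants — they fold in the twinfilin arrival/resolution cycle and
therefore depend on its concentration; the mechanistic BFCT/BCT pathway
and the coarse two-route description coexist deliberately.

## The synthetic-data generator

`simulate_trajectory()` is a plain Gillespie realization: exponential
sojourns at each state's total exit propensity, next state proportional
to edge propensity. `simulate_cohort()` runs one trajectory per filament
and extracts the per-filament event record (resolution time, route,
censoring at the window). Per-filament seeds come from a counter-based
scheme, `filament_seed(seed, i) = (seed + 100003 i) mod (2^31 - 1)`, so a
cohort is reproducible and order-independent.

The observation layer (`render_trace()`) emulates what a TIRF kymograph
analysis ultimately hands to the statistics: per-frame intensity values
for one channel (actin, formin, CP, twinfilin) or an integrated length
channel. A frame reports the channel's protein as present when
protein-occupied states cover the **majority of the frame interval** —
not an instantaneous sample — so events shorter than half a frame vanish
entirely, exactly the regime in which measured single-frame dwells are
lower bounds. Photobleaching is one irreversible exponential off-time per
fluorophore (configurable count, e.g. 2 for a dimeric formin label);
Gaussian noise is added per frame. `presence_ground_truth()` exposes the
same majority rule without noise or bleaching, which gives the tests an
exact oracle: with zero noise, `binarize_trace()` must reproduce it
frame-for-frame.

What the generator does *not* emulate: spatial structure (no kymograph
pixels, drift, or localization error), intensity heterogeneity between
fluorophores, blinking, nucleotide-state-dependent depolymerization, and
flow artifacts. Passing tests therefore validate the statistical
machinery under the model's own assumptions — exponential lifetimes,
independent visits, memoryless bleaching — not the microscopy itself.

Default parameters in `default_rates()` are anchored where measured
values exist: the control decision-complex lifetime of 149 s partitioned
by the observed 30:42 outcome counts, twinfilin residence means of 1.9 s
(`BCT`) and 1.4 s (`BFCT`), per-visit uncapping probabilities 1/30.9 and
1. Association rate constants (`k_on_C` = 10, `k_on_T` = 1 per uM per s)
and the per-state velocities are round demonstration values — no absolute
twinfilin on-rate has been measured — and are documented as such.

## Survival inference

`survival_curve()` builds the right-continuous empirical step function
`S(t) = 1 - (events ≤ t)/n0`; censored filaments keep the denominator but
never decrement the curve. `fit_single_exponential()` minimizes the
unweighted sum of squares between `S` at the event times and
`exp(-k t)` with amplitude fixed at 1 (survival fractions are already
normalized; fitting the dissociated fraction `1 - exp(-kt)` yields the
same minimizer, so only one form exists). Numerically the objective
flattens towards its asymptote for large `k`, so the minimizer is
bracketed by a 41-point log-spaced grid around a
regression-through-origin starting value before Brent refinement; a
non-decaying curve returns rate 0 with a `degenerate` flag rather than an
error. A censored maximum-likelihood estimator (`method = "mle"`) is kept
as a cross-check; on uncensored exponential data the two agree within a
few percent at realistic cohort sizes.

`decompose_routes()` splits the fitted total rate by the outcome counts
(`k'_C = k_BFC · N_BF/(N_BF+N_BC)`), using non-censored rows only for the
split. `bootstrap_rate_ci()` reproduces the parametric bootstrap used for
survival-fit uncertainties: simulate replicate cohorts of `n` exponential
lifetimes at the fitted rate, censor at the window, refit each, and
report the central 65% percentile interval plus the sd of the refit
distribution. The 65% level and the 1000-replicate default follow the
convention of the experiments being modeled; calibration of the interval
is itself a test (coverage of the generating rate across 1000 synthetic
cohorts of 50 filaments, with 500 bootstrap replicates per cohort to keep
the run affordable — the percentile interval is insensitive to the
replicate count well below that).

## Dwell-time and visit statistics

`binarize_trace()` thresholds a trace (default: midpoint of a 2-means
split of the intensity histogram, since real thresholds are
instrument-specific), merges on-runs across at most `gap_tolerance` off
frames (default 0 — raw arrivals and departures, no blinking correction)
and reports half-open frame intervals; single-frame intervals carry a
lower-bound flag. `dwell_summary()` averages *all* durations with no
outlier trimming. `visits_until_uncapping()` counts intervals starting at
or before the uncapping time — operationally defined, configurably, as
the first frame from which the length channel decreases for at least 3
consecutive frames — and `estimate_uncap_probability()` inverts the mean
visit count under the geometric model implied by independent visits, with
a nonparametric bootstrap over filaments. Mean dwell and sem are computed
globally over pooled events (a per-filament option would weight filaments
equally; the pooled convention matches how event histograms are reported).

One bias deserves emphasis. Under the majority-of-interval rule an event
of duration `d` registers `d/Δ` frames *in expectation*, but events
shorter than `Δ/2` register zero frames and can never be detected.
For exponential dwells of mean 1.9 s sampled at Δ = 0.2 s about 6% of
events are lost this way, and since the lost events are the shortest
ones, the detected mean is biased upward by roughly the same fraction
(the package's own tests measure ≈ +7% under exactly these conditions).
This is a property of frame-sampled single-molecule data, not of the
implementation; it is the quantitative face of the "single-frame dwells
are lower bounds" caveat, and it means frame-sampled dwell means should
be trusted only to within `Δ/(2·mean)`-level relative accuracy.

`count_bleach_steps()` is a deliberately simple QC heuristic (greedy
binary segmentation on a running mean, merge of sub-threshold segments,
count of downward level changes ≥ `min_step`) — adequate for the
single-versus-double-step classification used to verify label
stoichiometry, and not a general change-point method.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state; `run_pipeline()` is a pure function of its config and
embeds the config's MD5 hash and package version in every JSON output.
The test suite exercises parameter recovery at cohort sizes of 2,000
filaments (rate recovery within 10%), 1,000 synthetic cohorts for
bootstrap calibration, and 2,000 filaments for the geometric visit law —
sizes chosen to keep Monte-Carlo error a few times smaller than the
tolerances being checked.

```{r example}
rates <- default_rates()
sim <- simulate_cohort(rates, 500, "BFC", window = 1500, seed = 1)
decompose_routes(sim$events)
```

## Known limitations

* The two-route decomposition assumes a single exponential; mixtures
  (e.g. heterogeneous filament populations) are out of scope, as are
  Kaplan–Meier or Cox machinery.
* Observed rates under twinfilin are concentration-dependent composites;
  the package reports them as fitted, and recovering the microscopic
  visit parameters requires the dwell/visit analyses, not the survival
  fit alone.
* The bleach-step counter is a QC heuristic, not an HMM; heavily noisy
  or multi-level traces deserve a dedicated method.
* Frame-sampled dwell statistics carry the detection bias described
  above; interpret means near the frame interval as bounds.
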