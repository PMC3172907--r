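---
title: "Lifetime cancer risk from registry data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime cancer risk from registry data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amprisk)
```

## The four-state model

All quantities in this package live on a four-state illness–death model in
continuous age $t$:

* state 0 — alive, never had cancer;
* state C — alive with or after cancer;
* state D — dead of cancer;
* state X — dead of another cause.

Transition hazards (per person-year) are $\lambda_{0C}$ (first diagnosis),
$\lambda_{0X}$ (non-cancer death before any cancer), $\lambda_{CD}$ and
$\lambda_{CX}$ (cancer and non-cancer death after a diagnosis). A further
rate $\lambda_{CC}$ counts *new primaries* in people already in state C: it
fires events but does not change the state. The hazard $0 \to D$ is zero by
construction — one cannot die of cancer without ever having had it.

Writing $S_0(t)$ for the probability of still being in state 0 and $P(t)$
for the probability of being in state C, the **true lifetime risk** of a
first cancer is $\int_0^\infty \lambda_{0C}(u) S_0(u)\,du$ and the
**expected number of primaries** per lifetime is
$\int_0^\infty [\lambda_{0C} S_0 + \lambda_{CC} P]\,du$. Neither
$\lambda_{0C}$ nor $S_0$ is observable from routine registry output; what a
registry sees are the occupancy-weighted mixtures
$\lambda_C = (\lambda_{0C} S_0 + \lambda_{CC} P)/(S_0 + P)$ and
$\lambda_X = (\lambda_{0X} S_0 + \lambda_{CX} P)/(S_0 + P)$.

## The estimators

From age-banded counts the observable hazards are $\lambda_C = R/N$,
$\lambda_X = (M - D)/N$, $\lambda_M = M/N$. The three life-table estimators
integrate the registration rate against different survival-type curves:

* **current probability (CP)**: $\int \lambda_C S_{all}$ with $S_{all}$
  built from $\lambda_M$ — on all-primaries data this is the mean number of
  registrations per lifetime (it may exceed 1; the package warns rather
  than clips);
* **AMP**: $\int \lambda_C S^*$ with
  $S^* = \exp\{-\int(\lambda_C + \lambda_X)\}$, a proxy for being alive and
  not previously registered — always in $[0,1]$;
* **gold standard**: CP run on first-primaries-only counts (the function
  refuses all-primaries tables).

When $\lambda_{CC} = \lambda_{0C}$ and $\lambda_{CX} = \lambda_{0X}$ at all
ages, $\lambda_C = \lambda_{0C}$ and $\lambda_X = \lambda_{0X}$, so the AMP
integral *equals* the true lifetime risk; the package asserts this
consistency numerically. When the assumptions fail the error is second
order whenever the prevalence share $P/(S_0+P)$ is small; the reduction AMP
applies to CP is bounded by $\mathrm{CP}^2$, so a 3% CP estimate can fall no
lower than 97% of itself. AMP *overcorrects* for sites where repeat
primaries are essentially impossible (prostate-like), which is why the
validation command treats an AMP miss on such profiles as honest bias, not
a defect.

## Numerical choices

**Exact within-band integration.** All hazards are treated as piecewise
constant on the band grid, under which every integral has a closed form:
band $i$ contributes
$[\lambda_C/(\lambda_C+\lambda_X)]\,[S^*(a_i) - S^*(a_{i+1})]$ (0 when both
hazards vanish, by continuity of the $0/0$ ratio), and an open final band
contributes $[\lambda_C/(\lambda_C+\lambda_X)]\,S^*(a_K)$. This form is
invariant to splitting bands, which the tests assert; a trapezoid variant
(`rule = "trapezoid"`) exists purely for sensitivity checks. Truncated
estimates stop at the boundary with no tail term, and truncation ages must
sit on band boundaries (the error names the nearest ones).

**Occupancies without an ODE solver.** The generator of the four-state
model is triangular, so within a band the forward equations have closed
solutions built from two exponentials with rates
$\alpha = \lambda_{0C}+\lambda_{0X}$ and
$\beta = \lambda_{CD}+\lambda_{CX}$. The implementation uses
`expm1`-stable primitives and switches to the $\alpha = \beta$ limit form
when $|\alpha-\beta|$ is below $10^{-9}\max(\alpha,\beta,1)$ to avoid
cancellation. Occupancy evaluation is therefore exact at any age; the
`step` argument only controls output resolution.

**Independent oracle.** `fine_grid_oracle()` re-evaluates the AMP integral
by marching boundary-aligned cells of at most `step` years (default 1/1024)
and accumulating each cell's exact constant-hazard contribution — a second,
structurally different evaluation path that must agree with
`amp_estimate()` to $10^{-10}$ relative error.

**Rounding.** Raw probabilities are never rounded internally; reported
percentages round half away from zero at the displayed precision (matching
how published tables are typed), via `fmt_percent()`.

## The simulator and what it emulates

`simulate_cohort()` draws complete lifetimes by exact inversion of the
piecewise-constant cumulative hazard across band boundaries; event kinds
are drawn proportionally to the cause-specific hazards at the event age.
Everyone is followed to death: a `max_age` cap (default 120 years) forces a
non-cancer death so lifetime summaries are always defined. Individuals are
simulated in blocks of 25 000 with per-block seeds
`seed + (block-1) * 10007` (`sim_subseed()`), making runs reproducible and
block-decomposable.

`aggregate_registry()` converts histories into the two tables a registry
could publish (all primaries, first primaries). Counts are **annualized**:
a cohort crosses a band of width $w$ over $w$ years, so the mid-year
population analogue is person-years$/w$ and the annual counts are band
events$/w$; `count / population` is then exactly a per-person-year hazard,
and $\sum_i N_i w_i$ reproduces total simulated life-years. The open band
uses $w = 1$. What the simulator does *not* emulate: calendar time (no
period or cohort trends, no screening-induced incidence shocks of the
PSA-introduction kind — a cross-sectional "lifetime risk" is an artificial
construct wherever rates are changing), covariates or frailty (smoking and
deprivation jointly raise several cancer incidences and non-cancer
mortality, which is exactly how the AMP assumptions fail in real data), and
registry imperfections (late registrations, immigration of people with
unknown prior cancers, NMSC numerator/denominator conventions — the reader
only warns when the case and death site labels differ).

## The hazard archetypes

`hazard_profile()` ships four qualitative archetypes on 1-year bands to age
90 (open 90+), with Gompertz-like non-cancer mortality
$3\times10^{-4} + 4\times10^{-5} e^{0.092 t}$ and exponential-in-age
incidence curves evaluated at band midpoints. They are labelled archetypes,
not calibrations to any registry, but their scales are chosen to be
realistic: `baseline` has a true first-cancer risk of 0.416 and expected
primaries of 0.470 (an all-cancers-like "2 in 5" risk with a ~5-point
multiple-primary excess; equal rates hold exactly so AMP is consistent);
`breast_like` (risk 0.099) has elevated repeat primaries
($\lambda_{CC} = 1.6\lambda_{0C}$) and good survival, so CP overestimates;
`prostate_like` (risk 0.089) has $\lambda_{CC}=0$, so CP equals the gold
standard and AMP overcorrects; `lung_like` (risk 0.085) has doubled repeat
primaries and tripled post-diagnosis other-cause mortality, yet survival so
poor that all methods nearly coincide. The cancer-fatality hazards
$\lambda_{CD}$ are flat (0.15, 0.02, 0.03, 0.45 per year respectively) —
crude relative to real follow-up-dependent fatality, but sufficient for the
estimator contrasts these profiles exist to exhibit.

Validation problem sizes: the stochastic checks simulate 100 000 lifetimes
per profile and test at 3 Monte-Carlo standard errors, which separates the
CP bias (~5 points at baseline) from noise (~0.5 points) by an order of
magnitude while keeping the whole suite a matter of seconds.

## Open design choices

* The published banded estimation formula is typeset only as images in the
  source material; this package adopts the exact-under-piecewise-constant
  reconstruction above and validates it against the continuous definition
  (the fine-grid oracle) instead of against an unreadable display equation.
* Where the open band starts matters (85+ vs 90+ changes published 5-year
  estimates in the first decimal); `collapse_open_band()` makes the cap
  explicit and both are supported. Profile models start the open band at
  90.
* Multi-year period extracts must be pre-averaged to annual scale by the
  caller; published sources do not state their annualisation convention, so
  the package refuses to guess.
* Band membership at an exact boundary age goes to the upper band; counts
  are accepted as non-negative reals to support period-averaged data.
* No confidence intervals are produced: the estimators are deterministic
  functionals of the input table, and the source methodology publishes
  none. Monte-Carlo error enters only through the simulator, whose
  summaries report their own standard errors.
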