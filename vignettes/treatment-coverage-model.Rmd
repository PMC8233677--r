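---
title: "Modelling opium-dependence treatment coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling opium-dependence treatment coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opiumdyn)
```

## The model

`opiumdyn` simulates a national opium-dependent population in discrete
annual steps. The population is split into four mutually exclusive
compartments — methadone maintenance (MMT), buprenorphine maintenance
(BMT), detoxification with relapse prevention (DETOX), and untreated or
non-evidence-based care (UNTREATED). Every year,

1. **outcomes** are counted on start-of-year stocks: deaths
   (`stock × Ꝩ_g`), month-12 abstinence events (`stock × Ψ_g`), and heroin
   transitions from the untreated stock (`stock_W × Ɣ_W`);
2. **flows** are applied at year end: treated persons stay, die, or
   discontinue into the untreated pool;
3. **entries** occur at the start of the next year: the untreated pool
   redistributes across the four compartments by the annual entry shares
   Θ_g, and new dependents are added so that total dependence tracks a
   constant prevalence on a growing 15–64 population.

All rates are annual probabilities stored on the percent scale exactly as
tabulated, and converted to fractions only inside arithmetic — this avoids
transcription drift against the source tables. Stocks are continuous
(fractional persons); integers appear only in reports, rounded half-up to
match table conventions.

## Key structural decisions

**Abstinence is an event counter, not an outflow.** The discontinuation
derivation closes each treated group's flow balance with *stay + death +
discontinuation = 100* — retention is the "stay" quantity for the
maintenance groups and treatment success for DETOX, the only reading that
reproduces all three tabulated discontinuation values (65.93, 69.61,
89.47). That balance leaves no residual flow for abstainers, and total
dependence grows at the demographic rate, so abstinence must be an annual
indicator that leaves people in their compartments.

**Two advancement modes.** The source model's software implementation is
not fully specified, and its long-run trajectories cannot be recovered from
the printed parameter set alone. We therefore expose:

* `fixed_shares` (default) — quasi-static: each year's total is reallocated
  by the entry shares. Year-1 quantities are exactly reproducible, and all
  outcomes are linear in the coverage factor, which makes ±25% scenario
  shifts mirror-symmetric.
* `flow_based` — explicit stock-and-flow dynamics with a complete per-year
  ledger (deaths, heroin transitions, stayers, discontinuers, entries,
  replenishment). Conservation — `stock(t+1) = stock(t) − deaths − heroin +
  replenishment` — holds to 1e-9 relative and is property-tested on
  generated parameter sets.

Both modes share the initial allocation, so year-1 states and outcomes are
identical.

**Replenishment enters the untreated compartment only**: new dependents
have not yet sought treatment. The top-up is never negative; if stocks ever
exceeded the population target the advance raises an infeasibility error
rather than silently deleting persons.

**Demographic growth.** The growth rate is marked "calculate" in the source
table; the package defaults to the rate whose 29 annual increments give the
published 28.93% cumulative growth of the dependent population,
`calibrate_growth_rate(28.93, 29)` = 0.88005%/yr (verified in tests against
an independent root-finding oracle). An explicit per-year growth-factor
series can be supplied instead.

**`mortality_scale`.** The published year-1 status-quo death count is not
derivable from the tabulated death rates under any per-100 or per-1000
reading we tried; rather than silently altering printed rates, the package
provides a dimensionless multiplier on all death probabilities (default 1)
as an explicit calibration hook. Under a scale ≠ 1 the flow residual is
assigned to stayers so compartments never go negative.

**Scenario contrasts.** Coverage scenarios multiply the three treated entry
shares by a common factor (preserving the treatment mix) and renormalise
the untreated share; the default grid is ±25/50/75% around the 28.5% status
quo, i.e. coverage levels 35.63/42.75/49.88 and 21.38/14.25/7.13%. The
decade statistic is literally θ = Σ_t (B_t − A_t)/A_t over the ten years of
a decade, with the decade percentage change defined as θ × 10 — the rule is
implemented exactly as stated by its source, since no independent
definition exists. Baselines are always the factor-1 run of the same
parameters, horizon and mode; cross-mode comparisons are refused.

## Uncertainty propagation

The source reports 95% intervals without describing their generating
method, so the package makes its own, clearly labelled choice: parameter
perturbation Monte Carlo with percentile (2.5/97.5) intervals. Each rate is
drawn independently around its point value with a relative standard
deviation (default 5%, a placeholder exposed in `uncertainty_spec()` — no claim is made
of matching the original, unknown uncertainty inputs), either as a
truncated normal on the percent scale (default) or a moment-matched beta on
the fraction scale. Entry shares are renormalised to the 100% simplex and
discontinuation probabilities re-derived, so every draw is a valid
parameter set; invalid candidates are rejected with bounded retries.

Both arms of a contrast (baseline and scenario) use the *same* parameter
draw — common random parameters — which provably reduces contrast variance
(asserted in the tests). Draws are addressed by `(seed, draw_index)`
substreams, so results are order-independent and bit-for-bit reproducible.
The point estimate always comes from the unperturbed parameters, and
percentile intervals are not forced to bracket it. Published interval
bounds are therefore *not* reproduction targets.

## The synthetic-data generator and the microsimulation oracle

`random_parameter_set()` draws entry shares from a flat simplex and rates
uniformly within ranges constrained so every outflow balance can close
(retention + death ≤ 100; success + death ≤ 100 for DETOX); constraints can
pin any value, and pinning everything reproduces the packaged defaults
exactly. `random_growth_series()` emulates a fluctuating demographic rate.
The generator emulates *valid parameter sets*, not the epidemiology of any
real country: shares far from the national estimates, or rate combinations
never observed in practice, are deliberately in range. A green property
test therefore establishes structural correctness (conservation, validity,
monotonicity), not predictive accuracy.

`microsimulate()` is an individual-level implementation of the same annual
rules: one competing-event draw per agent per year (die; discontinue or
transition to heroin; else stay — identical marginal probabilities to the
deterministic rates), an independent abstinence event draw, reallocation of
discontinuers and untreated survivors by the entry shares, and replenishment
with new untreated agents. Counts are scaled by `initial_population /
n_agents`. Because flows are linear in stocks, the deterministic model is
exactly the microsimulation's expectation, and the suite checks agreement
within three binomial standard errors at 100,000 agents across twenty
generated parameter sets.

## Numerical choices

* Percent-scale storage; fraction conversion only inside arithmetic.
* Display rounding is half-up (`round_half_up()`), 2 decimals for
  percentages, integers for counts; internal values are never rounded.
* Entry-share simplex tolerance 1e-9 (percent scale); outflow balances
  1e-9; flow conservation 1e-9 relative; prevalence tracking 1e-6 relative.
* Relative change with a zero baseline year is flagged (`rel_defined =
  FALSE`, `NA` value) instead of propagating NaN; the decade statistic
  errors on a zero baseline year inside its window.
* Degenerate inputs: factor 0 and infeasible coverage (> 100% treated
  shares) are errors; an all-untreated parameter set is valid and inert.
* RNG: `set.seed()` on derived 32-bit substream seeds; Monte-Carlo draws
  and microsimulation runs are deterministic per seed.

## Known limitations

* The quasi-static `fixed_shares` mode ignores within-treatment carry-over;
  the `flow_based` mode models it but neither is claimed to reproduce the
  original multi-year trajectories, which are not derivable from the
  published parameter set.
* No age/sex structure, injection or HIV sub-models, behavioural feedback,
  or treatment-capacity constraints; prevalence is exogenous and constant.
* Parameter uncertainty is propagated independently per rate; correlations
  between rates are not modelled.
* Cost-effectiveness is out of scope.
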