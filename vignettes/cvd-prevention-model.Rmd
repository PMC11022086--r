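---
title: "A Markov cohort model of CVD screening and prevention: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of CVD screening and prevention: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Myanmar has no national cardiovascular disease (CVD) screening or
prevention programme, while stroke and ischaemic heart disease (IHD) are
its leading causes of death. `cvdprev` implements a decision-analytic
model that asks: starting from a community cohort of 45-year-olds with
unknown risk, what do screening, primary prevention and secondary
prevention cost per person, what health do they return, and what would a
national programme cost in its first years?

Four strategies are compared:

* **BASE** — no screening or prevention; acute events are still treated.
* **SC_PP_SP** — annual risk screening, primary prevention drugs for
  people at elevated 10-year risk, and secondary prevention for people
  with established CVD.
* **SC_PP** — screening and primary prevention only.
* **SP** — secondary prevention only.

## Model structure

The model is a closed-cohort Markov state-transition model with nine
mutually exclusive states and one-year cycles:

* `GEN` — general population, unknown/low (<10%) 10-year CVD risk;
* `R10`, `R20`, `R30`, `R40` — 10–19.9%, 20–29.9%, 30–39.9% and ≥40%
  10-year risk of an acute CVD event;
* `ACVD` — acute CVD event (acute coronary event or stroke), a
  **one-cycle tunnel**;
* `CHRONIC` — established (post-event) CVD;
* `CVD_DEATH`, `NONCVD_DEATH` — absorbing death states.

Permitted transitions: `GEN` feeds the four risk bands (annual,
sex- and age-band-specific incidences) and non-CVD death; each risk band
feeds `ACVD` at its annual acute-event probability and non-CVD death;
`ACVD` resolves within one cycle into CVD death (composite case
fatality), non-CVD death (background mortality among acute survivors) or
`CHRONIC`; `CHRONIC` can relapse to `ACVD` (recurrent-event probability)
or die of other causes. People never move between risk bands and never
return from `CHRONIC` to a risk band; `GEN` cannot jump directly to
`ACVD`. These structural zeros are asserted by the matrix builder, and
every row is checked to sum to one within 1e-12.

The cohort starts entirely in `GEN` at the starting age (45 by default;
55 and 65 for subgroup analyses) and is followed to age 100 — a 55-year
horizon from age 45. Later starting ages keep the same end age rather
than a fixed number of cycles.

## Parameters

`default_parameters()` returns the packaged national input set; every
probability is stored as a decimal. The pieces that matter most:

* **Risk-band incidence** (per year, by sex and band 45–54 / 55–64 /
  65+): the annual probabilities of being classified into each risk band.
* **Acute-event probabilities per risk band**: derived from the 10-year
  band midpoints (15%, 25%, 35%, 45%) under a constant-hazard assumption,
  `annual = 1 - (1 - p10)^(1/10)`, giving 1.61%, 2.84%, 4.22% and 5.80%
  per year. The ≥40% band is treated as 40–49.9%, whose midpoint (45%)
  reproduces the published 5.80% exactly.
* **Recurrent-event probabilities** from `CHRONIC`: 6.61% / 6.84% /
  10.88% per year by age band.
* **Background mortality** by sex and 5-year band (45–49 … 85+), and
  **case fatality rates** for acute stroke and acute IHD by sex and
  10-year band (40–49 … 80+). Band lookups use half-open intervals
  `[lo, next lo)` on integer ages with an open-ended top band.
* **Costs** (US$ per person-year unless noted): screening 9.13, primary
  prevention 38.62 (20–29.9% band) and 41.11 (≥30% bands), secondary
  prevention 41.28, acute-event treatment 449.40 per event, productivity
  loss 4,360 per event (societal perspective only).
* **Utilities**: 0.93 (`GEN`), 0.92/0.91/0.87/0.85 across the risk
  bands, 0.47 (`ACVD` year), 0.64 (`CHRONIC`), 0 in both death states.
* **Treatment effects** as relative risks: 0.47 (ACE inhibitor + calcium
  channel blocker + statin, 20–29.9% band), 0.36 (the same plus aspirin,
  ≥30% bands), 0.29 (secondary-prevention package) — see below for the
  semantics.
* **Discount rate** 3%/year for costs and outcomes;
  **willingness-to-pay thresholds** of US$1,400.2 (1× GDP per capita) and
  US$4,200.6 (3×) per QALY.

Parameter files are YAML (schema `cvdprev-params`, with a
`percent: true` dialect) or a tidy CSV table; both round-trip, and the
default set round-trips bit-identically.

### Treatment-effect semantics

The effect values are applied as **risk multipliers**: treated transition
probability = untreated probability × effect. Two observations force this
reading even though such values are sometimes labelled "relative risk
reduction": package effects are combined by *multiplying* individual
relative risks, and adding aspirin moves the primary-prevention value
from 0.47 to 0.36 — adding a drug must lower the multiplier, which is
incoherent if the values were reductions. The alternative reading
(probability × (1 − effect)) remains available via the
`effect_is_multiplier` configuration flag for sensitivity exploration.

### The composite case fatality and `stroke_weight`

Acute CVD pools stroke and IHD, whose case fatality rates differ by a
factor of ~3. The per-event death probability is
`w · CFR_stroke + (1 − w) · CFR_IHD` with `w = stroke_weight`. The
published mix of acute coronary syndrome and stroke behind the composite
is not printed, so `w` is a configuration knob. Its default, 0.3, is
calibrated once against the published budget-impact table, whose
deaths-averted/events-averted ratio (≈0.50) implies a composite case
fatality near 0.5 at typical event ages; that requires a stroke share
near 0.3. It was fixed before the cost-effectiveness comparisons were run
and is not adjusted per analysis.

### Other conventions

* **No half-cycle correction**: membership is full-year by assumption,
  so none is appropriate.
* **Discounting**: `d(t) = (1 + r)^{-t}` with `t = 0` for the first
  cycle (first year undiscounted). `discount_first_cycle = TRUE` discounts
  every cycle once instead. The immortal, utility-1 cohort then
  accumulates `\sum_{t=0}^{54} 1.03^{-t} = 27.58` discounted QALYs over
  55 cycles — a closed form the test suite checks to 1e-12.
* **Competing risks in the acute year**: case fatality is applied first;
  background mortality applies to acute survivors. Background mortality
  inside the acute year can be switched off
  (`acvd_background_mortality = FALSE`) because published model diagrams
  of this kind are ambiguous about it; the default applies it, reading
  "non-CVD death from all health states" literally.
* **Event costing**: the acute treatment cost (449.40) is charged per
  incident event in *all* scenarios including base. Productivity loss
  attaches per incident event under the societal perspective only; the
  base-scenario gap between published societal and provider costs
  (≈327 ≈ 0.075 discounted events × 4,360) supports this reading. A flag
  (`productivity_loss_on_death`, default off) can additionally attach it
  to CVD-death years.
* **Sex aggregation**: men and women are modelled separately and
  combined as a convex combination with `male_fraction` (default 0.48,
  the census order of magnitude) on the male result.

## Cost-effectiveness analysis

`evaluate_strategy()` accumulates discounted costs and QALYs;
`efficiency_frontier()` classifies strategies: sort by ascending cost,
mark strong dominance (no cheaper-or-equal strategy with at least equal
QALYs; equal-QALY/higher-cost is folded into strong dominance),
then iteratively remove extended-dominated strategies until frontier
ICERs strictly increase. `net_monetary_benefit()` is
`QALY × λ − cost`. The frontier produced this way provably equals the set
of max-NMB strategies over all thresholds; the test suite checks that
equivalence against an exhaustive oracle on random instances. Pairwise
ICERs against a fixed comparator (`pairwise_icers()`) are a secondary
output used for starting-age subgroup comparisons.

With the packaged defaults the model reproduces the published
deterministic league tables closely: provider-perspective costs/QALYs
within a few percent, the same dominance pattern in both perspectives
(screening+primary extended-dominated from the provider perspective;
base and screening+primary strongly dominated from the societal
perspective), and provider frontier ICERs within ~1% (≈158 and ≈1,572
US$/QALY for secondary prevention vs base and the full programme vs
secondary prevention). Residual deviations concentrate in the *societal*
incremental costs, which depend on unpublished conventions (the acute
stroke:IHD mix and productivity-loss timing); the societal frontier ICER
comes out ≈790 vs ≈647 US$/QALY published. One likely contributor: the
published female background-mortality table prints identical values for
the 70–74 and 75–79 bands, which looks like a duplication; this package
transcribes the printed value.

## Probabilistic sensitivity analysis

Each uncertain parameter gets a moment-matched distribution: **gamma**
for costs (relative SE 100%), **beta** for utilities and all
probabilities (relative SE 10%), **lognormal** for treatment effects
(relative SE 10%). The published specification gives no SE for transition
probabilities; 10% (the utilities/effects column) is the documented
default, configurable via `psa_spec$se_rel_tp`. Moment matching is
analytic (`moment_match()`), with a hard error on infeasible beta
moments; draws are never truncated — a draw that violates a joint
invariant (e.g. the strict ordering of acute-event probabilities across
risk bands) causes the whole set to be resampled.

`run_psa()` uses common random numbers across strategies: one parameter
draw feeds all scenarios and both sexes, since the strategies share the
same underlying quantities. Each draw seeds its own RNG substream from a
mix of the base seed and the draw index, so any draw is reproducible
independently and the run is bit-reproducible given the seed; zero SEs
collapse the PSA to the deterministic result exactly.

`ceac()` reports, per strategy, sex and threshold, the fraction of draws
whose NMB strictly exceeds the *base scenario's* (pairwise comparator).
The pairwise definition is deliberate: published acceptability
probabilities for the three intervention strategies at one threshold sum
to well over 100%, which rules out a
max-NMB-among-all definition; that variant is still available via
`rule = "max_nmb"`. At 10,000 draws the secondary-prevention curve
against base exceeds 98% at the 1× GDP threshold for both sexes, the
result the acceptance script recomputes.

## Budget impact analysis

`budget_impact()` works on national eligible pools (screening
10,948,870; primary prevention 820,106 in the 20–29.9% band and
1,184,545 in the ≥30% bands; secondary prevention 31,306 under the full
programme or 57,152 standalone — the two secondary-prevention counts are
independent published inputs). Per year:

* intervention budget = coverage × pool × per-person annual cost;
* one-year acute events per pool from the engine's transition
  probabilities (the ≥30% pool splits 50:50 between the 30–39.9% and
  ≥40% bands by default, `pp_high_r40_share`); with intervention, events
  in the covered fraction scale by the scenario's relative risk;
* disease-cost offset = events × 449.40; **budget impact = intervention
  cost − offset**, an identity the tests hold to the cent;
* deaths averted = events averted × composite case fatality at the
  reference age (55 by default), sex-mixed by `male_fraction`.

Years 2–3 advance each pool under *untreated* dynamics (attrition by
events and background mortality at the reference age), a deliberate
simplification that keeps every output exactly linear in coverage —
halving coverage halves budgets and benefits, matching the published
half-coverage figures' behaviour. Pool migration (event survivors joining
the secondary-prevention pool) is not modelled; over a 3-year horizon the
effect is small relative to the uncertainty in the pools themselves.
`bia_accounting()` applies the identity directly to component totals, and
reproduces the published Year-1 budget impacts to ±1 US$ from the
published components. `derive_eligible_populations()` builds the pools
from a census-like table and prevalence shares (defaults calibrated to
the published national counts).

## Synthetic data

`perturbed_parameters(seed, scale)` multiplies each stochastic parameter
by an independent uniform factor in `[1 − scale, 1 + scale]`, resampling
on range or invariant breaches; scale 0 is the identity. It deliberately
avoids the PSA's distributional machinery so property tests of the PSA do
not test it against itself. `generate_population(total)` builds a
sex × 5-year-band table decreasing geometrically with age
(default decay 0.78 per band — a plausible monotone shape, not a model of
any real census age structure), with largest-remainder rounding so totals
are exact. These generators emulate schema and magnitudes, not real-world
correlation structure: passing property tests demonstrates internal
consistency of the machinery, not calibration to real data.

## Problem sizes and runtime choices

The deterministic analysis is instant. The test suite runs the full
10,000-draw PSA (4 strategies × 2 sexes, ≈3 minutes on one core) for the
acceptability check, 1,000 randomized parameter sets for the
row-stochasticity/conservation sweep, and 10^6-draw sampling checks for
the moment-matching; the acceptance script re-runs the 10,000-draw PSA
for the two strategies it needs (≈1.5 minutes). Transition matrices are
rebuilt per cycle but cached per distinct age-band profile (≈10 distinct
matrices per 55-cycle run), which is what makes the PSA affordable in
plain R.

## Known limitations

* No movement between risk bands, no treatment-adherence decay, no
  prevalent disease at baseline — the cohort starts entirely unknown-risk.
* The acute stroke:IHD mix, productivity-loss timing and census weights
  are configuration knobs with documented defaults, not printed facts;
  societal-perspective increments are the most sensitive outputs.
* The budget impact is a point estimate (no uncertainty propagation) and
  ignores economies of scale, migration between pools, and demographic
  inflow after Year 1.
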