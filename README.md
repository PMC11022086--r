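# cvdprev

A Markov cohort cost-effectiveness and budget-impact model of
cardiovascular disease (CVD) screening, primary prevention and secondary
prevention for a low-resource health system, with Myanmar's published
national inputs as the packaged default parameter set.

It is written for health economists and modellers who want a tested,
scriptable implementation of this class of analysis: a nine-state
state-transition model, deterministic cost-effectiveness analysis with
dominance classification and net monetary benefit, probabilistic
sensitivity analysis (PSA) with cost-effectiveness acceptability curves
(CEACs), subgroup analysis by sex and starting age, and a Year 1–3
budget impact analysis (BIA).

## The model

A closed cohort starts at age 45 in a general population of unknown CVD
risk and moves through nine states in one-year cycles: `GEN`, four
10-year-risk bands (`R10` = 10–19.9%, `R20` = 20–29.9%, `R30` =
30–39.9%, `R40` = ≥40%), an acute-event tunnel state `ACVD`, established
disease `CHRONIC`, and two absorbing death states. Per cycle, for state
occupancy $\pi_t$ and age-specific transition matrix $P_t$:

$$\pi_{t+1} = \pi_t P_t,\qquad
\mathrm{QALY} = \sum_t (1+r)^{-t}\,\pi_t u,\qquad
\mathrm{Cost} = \sum_t (1+r)^{-t}\left(\pi_t c + e_t\,c_{\mathrm{ACVD}}\right)$$

with utilities $u$, annual state costs $c$ per scenario and perspective,
new acute events $e_t$, and discount rate $r = 3\%$ (first cycle
undiscounted). Four strategies are compared — no programme (`BASE`),
screening + primary + secondary prevention (`SC_PP_SP`), screening +
primary prevention (`SC_PP`), and secondary prevention only (`SP`) —
via the efficiency frontier (strong and extended dominance, incremental
cost-effectiveness ratios, ICERs) and net monetary benefit
$\mathrm{NMB}(\lambda) = \lambda\,\mathrm{QALY} - \mathrm{Cost}$ at the
1× and 3× GDP-per-capita thresholds (US$1,400.2 and US$4,200.6/QALY).
Treatment effects enter as risk multipliers on the treated transitions
(0.47 and 0.36 for the two primary-prevention packages, 0.29 for
secondary prevention). See the vignette
(`vignettes/cvd-prevention-model.Rmd`) for assumptions, conventions and
design notes.

## Worked example

```r
library(cvdprev)

ps  <- default_parameters()                      # packaged published inputs
res <- evaluate_strategies(ps, perspective = "provider")
league_table(res[, c("strategy", "cost", "qaly")], ps$wtp_thresholds)
#>   strategy     cost    qaly             status     icer nmb_gdp1 nmb_gdp3
#> 1     BASE  32.9674 17.3934           frontier       NA  24321.2  73029.6
#> 2       SP  37.1416 17.4198           frontier  158.197  24354.0  73136.3
#> 3    SC_PP 230.9869 17.5279 extended_dominated       NA  24311.6  73396.7
#> 4 SC_PP_SP 233.6425 17.5447           frontier 1572.439  24332.5  73464.7
```

Read: without any programme a person accrues US$32.97 of discounted
acute-care cost and 17.39 discounted QALYs over the 55-year horizon.
Secondary prevention adds 0.026 QALYs for US$4.17 (ICER ≈ US$158/QALY —
cost-effective even at 1× GDP per capita, where its NMB of 24,354 is the
highest). The full programme is the frontier strategy at ≈US$1,572/QALY,
cost-effective at the 3× GDP threshold (highest `nmb_gdp3`);
screening+primary prevention alone is extended-dominated.

The budget impact of the full programme at national scale, Year 1:

```r
budget_impact(default_bia_inputs("SC_PP_SP"), "SC_PP_SP", ps)
#> <cvd_bia> SC_PP_SP, coverage 1, horizon 1 year(s)
#>        intervention_cost cost_saving budget_impact events_averted deaths_averted
#> year1          181624633    23299516     158325117          51846          27629
```

Screening ~10.9 million people and treating the eligible pools costs
US$182M; averting ~52,000 acute events saves US$23M of acute care, for a
net budget impact of US$158M and ~28,000 CVD deaths averted.

Probabilistic analysis:

```r
res <- run_psa(ps, n_draws = 10000, seed = 1)    # ~3 min on one core
ceac(res, comparator = "BASE", wtp_grid = default_wtp_grid(ps))
```

gives, per strategy, sex and threshold, the probability of being
cost-effective against no programme; at US$1,400.2/QALY the
secondary-prevention curve is ≥98% for both sexes.

Reports (`run_cea_report()`, `run_psa_report()`, `run_bia_report()`,
driven by `run_config()`) write the same tables as provenance-stamped
CSVs; `inst/cli/cvdprev.R` is a thin command-line wrapper over them.

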