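# pdcua

Lifetime Markov cohort modelling for the economic evaluation of peritoneal
dialysis (PD) strategies in end-stage renal disease (ESRD) patients with
fluid and sodium overload.

Patients who retain fluid on glucose-based continuous ambulatory peritoneal
dialysis (CAPD) can be switched to an icodextrin exchange (CAPD+ICO) or to
automated peritoneal dialysis (APD) — both substantially more expensive in
the Thai health system. `pdcua` implements the decision model a health
technology assessment of that choice requires, for analysts who want the
spreadsheet-style cohort model as programmable, tested code:

* a **six-state annual-cycle Markov cohort engine** (CAPD, CAPD+ICO, APD,
  haemodialysis, kidney transplantation, death) with per-strategy transition
  schedules for trial years 1–3 and a steady-state extrapolation beyond;
* **cost-utility analysis**: discounted lifetime costs, life years (LY) and
  quality-adjusted life years (QALY), incremental cost-effectiveness ratios
  (ICER) and dominance classification;
* **costing transformations**: charge-to-cost conversion, CPI inflation,
  THB→USD reporting, and human-capital valuation of informal care;
* **uncertainty analysis**: one-way (tornado) sensitivity analysis,
  probabilistic sensitivity analysis (PSA) with cost-effectiveness planes
  and acceptability curves (CEAC), mortality-inflation and external-input
  scenario analyses;
* **budget impact analysis**: undiscounted 10-year projection of the
  payer's incremental expenditure.

## The model

A cohort starts at age 55 with all mass in its strategy's own PD state and
evolves by annual row-stochastic transition matrices,

```
pi_{t+1} = pi_t P_t ,
```

where `P_t` is the trial-year matrix for cycles 0–2 and a steady-state
matrix afterwards (steady death probability = mean of the three observed
annual death probabilities; other destinations held at year-3 values and
renormalised). Occupancy at the start of cycle *t* earns that cycle's costs
`c(s, t)` and utilities `u(s, t)`, discounted at rate *r* (3%/yr default,
first cycle undiscounted):

```
Cost  = sum_t (1 + r)^-t  sum_s pi_t(s) c(s, t)
QALY  = sum_t (1 + r)^-t  sum_s pi_t(s) u(s, t)
ICER  = (Cost_B - Cost_A) / (QALY_B - QALY_A)
```

A strategy is *dominated* when it costs more and yields fewer QALYs. Net
monetary benefit `NMB = lambda * QALY - Cost` at willingness-to-pay
`lambda` (160,000 THB/QALY, the Thai threshold) ranks strategies per PSA
iteration.

The trial's full parameter table is not public, so the package ships an
explicitly **synthetic** fixture (`fixture_parameters()`, also under
`inst/extdata/synthetic_fixture/`): the twelve published annual death and
HD-transfer probabilities are embedded verbatim (provenance `"trial"`),
everything else is a documented placeholder of realistic magnitude
(provenance `"placeholder"`). Results computed from the fixture are
therefore illustrative of the model mechanics, not a reproduction of the
published totals.

## Worked example

```r
library(pdcua)

params <- fixture_parameters()   # or load_parameters("config.json")
run_cua(params)
#> Cost-utility analysis (reference: CAPD )
#>
#>  strategy      cost   ly qaly discount_rate
#>      CAPD 2,679,224 4.21 3.17          0.03
#>  CAPD_ICO 4,518,306 6.29 4.71          0.03
#>       APD 2,810,745 3.96 2.85          0.03
#>
#> Incremental vs CAPD :
#>  strategy incremental_cost incremental_ly incremental_qaly
#>  CAPD_ICO        1,839,082           2.08             1.54
#>       APD          131,521          -0.25            -0.33
#>          icer_per_qaly dominance
#>              1,196,239      none
#>  Dominated ( -400,637) dominated
```

On the synthetic fixture, CAPD+ICO costs 1.84 million THB more than
glucose-based CAPD over a lifetime and gains 1.54 QALYs — an ICER of about
1.2 million THB per QALY, far above the 160,000 THB threshold, so it is not
cost-effective; APD costs more and yields fewer QALYs, so it is dominated.
Both qualitative conclusions match the published analysis.

Every result object is a tibble or has `tidy()`/`glance()` methods and an
`autoplot()` display:

```r
cumulative_mortality(run_cohort(params, "CAPD"), 55:58)
#> # A tibble: 4 x 2
#>     age cumulative_mortality
#>   <int>                <dbl>
#> 1    55                0
#> 2    56                0.167
#> 3    57                0.371
#> 4    58                0.523

convert_currency(c(160000, 908440))
#> # A tibble: 2 x 3
#>      thb    usd usd_rounded
#>    <dbl>  <dbl>       <dbl>
#> 1 160000  4603.        4603
#> 2 908440 26136.       26136

psa <- run_psa(params, iterations = 1000, seed = 1)
autoplot(psa, "ceac")                       # acceptability curves
autoplot(run_owsa(params), top = 10)        # tornado diagram
autoplot(budget_impact(675, 741250, 650000))
```

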