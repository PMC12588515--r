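---
title: "Methods: a lifetime Markov cohort model for peritoneal dialysis strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cohort model for peritoneal dialysis strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcua)
```

## The decision problem

End-stage renal disease patients on glucose-based continuous ambulatory
peritoneal dialysis (CAPD) who retain fluid and sodium can be switched to a
daily icodextrin exchange (CAPD+ICO) or to automated peritoneal dialysis
(APD). Both alternatives cost substantially more in the Thai health system,
so the choice is a cost-utility question: do the extra quality-adjusted
life years justify the extra lifetime cost at the Thai societal
willingness-to-pay threshold of 160,000 THB per QALY?

`pdcua` answers it with a cohort state-transition model. Six mutually
exclusive health states — the three PD modalities, haemodialysis (HD),
kidney transplantation (KT), and death — capture the renal replacement
pathway. A strategy is the modality a patient starts on; the whole cohort
begins in that state at age 55.

## Model structure and assumptions

* **Annual cycles.** Transitions happen once per year. Cycle 0 spans ages
  55–56; the occupancy at the *start* of a cycle earns that cycle's costs
  and utilities. This cycle-start convention matches common spreadsheet
  Markov practice; no half-cycle correction is applied, since the model
  this package re-implements uses none.
* **Structural mask.** PD states may move to any PD state, HD, KT or
  death; HD to HD, KT or death; KT only to KT or death; death is
  absorbing. Temporary transfers (a short HD spell during peritonitis with
  return to PD) are not represented. Whether PD-to-PD switches should be
  allowed symmetrically in every arm is not structurally determined, so
  `transition_mask(allow_pd_switch = FALSE)` lets an analyst forbid them;
  the default allows them, matching the pathway description.
* **Three observed years, then steady state.** Trial follow-up covers
  model years 1–3. From year 4 the annual death probability is the mean of
  the three observed annual death probabilities; all other destinations
  keep their year-3 values, rescaled proportionally over the non-death
  mass so each row still sums to 1. The mortality part of this rule is the
  source model's stated assumption; holding the remaining transitions at
  year-3 values (rather than a 3-year average) is this package's choice,
  made because only the mortality rule is stated and year 3 is the most
  recent observation. The degenerate case — a year-3 row with no survivors
  but a 3-year mean death below 1 — leaves nothing to rescale, so the
  residual survival mass stays in place.
* **Horizon.** The simulation stops at age 100 (45 cycles) or when the
  alive mass falls below 1e-9, whichever comes first. "Lifetime" is
  otherwise undefined for this model; the cap is configurable via
  `econ_settings(max_age = )` because base-case totals are mildly
  sensitive to it.

## Economics

Discounting uses exponent `t = 0` for the first cycle (first-year flows
undiscounted), the standard spreadsheet convention; costs and QALYs share
the 3%/yr rate per Thai HTA guidance. All accumulation is in THB;
`convert_currency()` is a reporting layer only (1 THB = 0.02877 USD, 2023),
which avoids compounding rounding — and explains why a single THB ICER can
correspond to two slightly different published USD figures depending on
where rounding was applied.

Billed hospital charges become economic costs through a cost-to-charge
ratio of 1.63. The published phrasing does not pin down the direction of
that conversion; since a ratio above 1 means charges exceed costs,
`charge_to_cost()` divides by default, and
`econ_settings(charge_direction = "cost_over_charge")` flips it. Informal
care is valued by the human-capital method: caregiving hours times an
hourly wage of GNI per capita divided by 52 weeks and a 48-hour week. The
default GNI per capita, 249,600 THB/yr, is the 2023 Thai figure (about
7,180 USD) rounded to a whole hourly wage of 100 THB.

`cua_table()` classifies a comparator as *dominated* when it costs more
and yields fewer QALYs and still reports the signed ratio, as published
tables customarily print it. A zero QALY difference yields an infinite
(undefined) ICER, not an error. Budget impact multiplies the eligible
population by the per-patient annual cost difference, holds the population
constant over 10 years, and never discounts.

## The synthetic parameter fixture

The source trial's full parameter table is not public. The package
therefore ships a deterministic, explicitly synthetic stand-in,
`fixture_parameters()`, whose design rules are:

* The twelve published annual probabilities are embedded verbatim with
  provenance `"trial"`: death in years 1–3 for the CAPD arm (0.1667,
  0.2449, 0.2424) and the CAPD+ICO arm (0.1167, 0.1633, 0.1212), and HD
  transfer for the same arms (0.0167, 0.0408, 0.1515 and 0.0500, 0.1020,
  0.2424).
* Published mortality is *arm-level*, so within an arm the same annual
  death probability applies to every alive state. This reads the trial
  evidence at the level it was reported and makes the three-year
  cumulative mortality of an arm exactly
  `1 - (1-p1)(1-p2)(1-p3)`.
* The APD arm's probabilities (death 0.1833/0.2653/0.2528, HD transfer
  0.0333/0.0714/0.1818), the PD-switch rate (0.01/yr to each other
  modality), and transplant rates (0.005/yr) are placeholders, chosen once
  so that APD tracks slightly worse survival than CAPD — the direction the
  published life-year totals imply — at rates plausible for Thailand's
  transplant capacity. All carry provenance `"placeholder"`.
* Costs are per occupied state (THB/yr, 2023): PD states around
  510–660 thousand, HD 700 thousand plus higher travel costs, KT
  300 thousand in the transplant year then 250 thousand. The icodextrin
  component is explicit: replacing one 200-THB glucose exchange per day
  with a 450-THB icodextrin bag adds (450 − 200) × 365 = 91,250 THB/yr.
  These magnitudes put lifetime discounted totals in the 2.5–4.5 million
  THB range of the published analysis without reproducing it.
* Utilities decline gently over the first three years (CAPD 0.78→0.76,
  CAPD+ICO 0.80→0.78, APD 0.74→0.70 — APD fastest, consistent with the
  reported quality-of-life trajectory), HD 0.70, KT 0.85, death 0.

What passing tests on this fixture show is that the *machinery* is right —
transition arithmetic, discounting, dominance, sampling, scenario
plumbing — and that the qualitative conclusions (CAPD+ICO far above the
threshold, APD dominated) follow from the published probabilities plus
plausible economics. They do not show that the package reproduces the
published totals, which depend on the unavailable table; the fixture makes
no attempt to match them and its totals should never be quoted as the
published ones.

## Uncertainty analysis

* **Distribution families** are an analysis choice, not published content:
  beta for utilities, gamma for costs (both moment-matched to mean and
  standard error), Dirichlet for transition rows with concentration equal
  to `psa_row_n` (default 60, the trial's per-arm size) preserving the row
  mean. Families and the concentration are configurable per parameter set.
  When no standard error is known the default is 20% of the mean, a common
  HTA convention.
* A beta moment match is infeasible when `se^2 >= m(1-m)`; the draw then
  falls back to a uniform on the clipped interval `m ± sqrt(3) se`
  (variance-matched) with a note.
* After a transition row is re-drawn, the steady-state rows are re-derived
  from the drawn years 1–3, so the extrapolation rule is honoured inside
  the PSA as well.
* **CEAC** ranks strategies by net monetary benefit per iteration; ties
  break toward the cheaper strategy — deterministic and conservative
  toward the cheaper option. The default willingness-to-pay grid runs 0 to
  1.6 million THB in 10,000-THB steps (ten times the threshold) and
  contains 160,000 exactly.
* **One-way analysis** re-runs the full lifetime model at each bound — no
  linearisation shortcut. Default bounds are mean ± 20%, documented rather
  than inferred, because the published tornado ranges are unstated. Bounds
  that would breach an invariant (a probability above 1) are clipped to
  the boundary with a note. Varying one transition probability rescales
  the rest of its row proportionally to keep it stochastic.
* **Scenarios.** Mortality inflation multiplies the steady-state death
  probability by `1 + f` (`f` in \[0, 1\]), capped at 1, rescaling the
  remaining destinations; `f = 0` is written so the base case is
  reproduced bit-identically (the scaling ratio is computed before the
  multiplication, so it is exactly 1). External-input scenarios accept
  age-indexed death probabilities — mapped to cycles via the starting
  age — and replacement utility tables.

## Numerical conventions

* Row-stochasticity is enforced at 1e-9 on input and holds at 1e-12 for
  generated schedules; trace mass conservation is tested at 1e-9.
* The engine matrix-propagation agrees with a naive per-state bookkeeping
  loop to 1e-12; the constant-hazard life expectancy identity `E[L] = 1/p`
  holds to 1e-6 when run to extinction.
* USD reporting rounds half-away-from-zero to whole dollars; the unrounded
  value is returned alongside.
* Parameter files are plain CSV (long format, UTF-8, `.` decimal) plus a
  JSON config. Doubles are written at 17 significant digits and parsed
  back through `strtod`, so write/load round-trips are bit-exact.

## Problem sizes used by the test-suite

Property-style tests run the engine-versus-oracle comparison on 100 random
parameter sets, validate 100 random generator outputs, and exercise file
round-trips on 25; the PSA tests use 3–60 iterations where the property
under test is distributional and the acceptance script uses the full 1,000
iterations of the published design. These sizes were chosen to exercise
each property densely while keeping the default suite quick to run.

## Known limitations

* The fixture's non-published values are placeholders; analyses needing
  the real parameter table must supply it via `load_parameters()`.
* Arm-level mortality applied to every alive state ignores state-specific
  survival differences (a KT recipient in the CAPD arm shares the arm's
  death probability), a simplification the fixture documents.
* No patient-level microsimulation, tunnel states or time-in-state memory;
  no extended-dominance frontier beyond pairwise comparisons of the three
  strategies; no expected-value-of-perfect-information analysis.
* Utilities enter as numbers; EQ-5D-5L scoring from questionnaire
  responses is out of scope.
* The external-validation comparison against observed cohort data requires
  that external dataset and is therefore limited here to producing the
  modelled cumulative mortality curves (`plot_mortality_curves()`).
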