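---
title: "Methods: a Markov cost-utility model of Achilles tendon rupture management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-utility model of Achilles tendon rupture management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendocea)
```

## The decision problem

Acute Achilles tendon rupture can be managed with open operative repair or
non-operatively, with both arms following an accelerated functional
rehabilitation protocol. Surgery lowers the re-rupture risk but raises
complication risk and adds hospitalization costs; non-operative care avoids
the operating room but keeps patients off work longer. `tendocea` implements
a cohort-level cost-utility comparison of the two strategies from the
societal perspective in 2014 US dollars: expected costs and
quality-adjusted life years (QALYs) are accrued over a 2-year horizon
divided into eight 3-month Markov cycles, without discounting (the horizon
is too short for discounting to matter materially).

## Model structure

The cohort is tracked over an expanded state space of pathway ×
cycles-since-last-treatment:

* **recovering** — the single cycle immediately following any treatment
  (primary management or re-rupture surgery). Utility 0.7.
* **full benefit** — treatment succeeded; utility follows the recovery
  schedule (0.8 in the second cycle after treatment, 0.9 thereafter).
* **minor complication** (superficial infection, transient pain, painful or
  hypertrophic scar) — scheduled utility × 0.9.
* **major complication** (deep venous thrombosis, pulmonary embolism, deep
  infection, sural nerve injury) — scheduled utility × 0.8.

At the end of the recovering cycle the episode resolves into full benefit,
minor complication, major complication or re-rupture, with probabilities
taken from the per-arm event rates (operative 3.8 / 5.5 / 15.4%,
non-operative 9.6 / 3.1 / 4.3% for re-rupture / major / minor). Re-ruptured
mass undergoes surgery at the start of the next cycle regardless of the
initial strategy: the re-rupture episode cost is charged, the utility clock
resets to 0.7, and the mass re-enters the lottery one cycle later with
*operative* probabilities. Re-rupture can recur in every subsequent
generation until the horizon truncates the recursion; no artificial depth
cap is applied.

Costs accrue as: the initial episode total in cycle 1 (hospitalization +
surgeon + physical therapy + missed work); one re-rupture episode total per
re-rupture surgery; and a one-off complication event cost when a
complication arises. QALYs accrue as occupancy × utility × 0.25 years per
cycle.

### Timing conventions and degenerate inputs

Several timing details are not dictated by the published description and are
fixed here as package conventions:

* Every episode resolves at the end of its first post-treatment cycle
  (re-ruptures are documented to occur within the first three months;
  complication timing is chosen symmetrically).
* The lottery is *not* drawn at the end of the final cycle: all of its
  consequences (costs and utilities alike) would fall outside the horizon.
  Expected re-rupture surgeries within the horizon therefore follow the
  truncated geometric series `q·(1 + p + … + p^6)` with first-episode
  probability `q` and operative follow-on probability `p`.
* Complication states are absorbing to the horizon by default. The
  alternative reading — the decrement applies for a single cycle — is
  available as `complication_persistence = "single_cycle"` in
  `utility_schedule()`. The absorbing default back-calculates to within
  0.02 QALYs of the published per-arm totals (see below).
* Missed-work costs accrue once per treatment episode, in the episode's
  first cycle; re-rupture surgery adds its own 8 missed weeks on top of the
  initial episode's weeks (the published cost table lists a separate
  missed-work line for the re-rupture column).
* Every occupancy row must sum to 1 within 1e-9; the engine aborts
  otherwise. Event-rate vectors must sum to strictly less than 1 per
  episode, so "certain re-rupture" stress scenarios use a probability of
  0.999999 and the matching closed form.

Running the model with all event rates at zero gives the closed form
`0.25 × (0.7 + 0.8 + 6 × 0.9) = 1.725` QALYs and a cost equal to the episode
total, which the test suite asserts exactly; an independent brute-force
oracle in the suite enumerates every pathway branch (re-rupture chains
included) and must agree with the matrix engine to 1e-9.

## Parameters

All inputs live in a single `ats_parameters()` object, constructed verbatim
from the published tables by `base_case_parameters()`:

| quantity | default | notes |
|---|---|---|
| cycle length / horizon | 0.25 y / 2 y (8 cycles) | `run_settings()` |
| non-operative rates | 9.6 / 3.1 / 4.3 % | re-rupture / major / minor, per episode |
| operative rates | 3.8 / 5.5 / 15.4 % | verbatim; derivable as RR × non-operative |
| risk ratios | 0.40 (0.12–1.32), 1.79 (0.64–5.01), 3.54 (0.40–31.61) | operative vs non-operative |
| hospitalization | $3145 (CI 3045–3244) op; $3944 re-rupture; $0 non-op | 2014 USD |
| surgeon | $810 op and re-rupture; $283 non-op | re-rupture reuses the primary fee |
| physical therapy | $821 | 24 sessions, all episodes |
| wage | $24.48125/h × 40 h/wk | exact value implied by $7834 / 8 weeks |
| weeks missed | 8 op, 10.5 non-op, 8 re-rupture | |
| utilities | 0.7 / 0.8 / 0.9 by cycle since treatment | minor ×0.9, major ×0.8 |
| WTP grid | $50,000 and $100,000 per QALY | |

The operative rate column is kept verbatim rather than derived because the
published columns are not mutually consistent (3.54 × 4.3% = 15.2%, printed
15.4%); the derivation is available via `derive_rates = TRUE` and
`derive_operative_rates()`. The hourly wage is stored at full precision
(24.48125, not the rounded $24) so every printed missed-work cost is
reproduced to within a dollar; missed-work components are always recomputed
from the wage model so that wage sweeps propagate into all three episode
kinds. Money is carried at full double precision internally and rounded
only for display.

## Calibrating the complication event costs

The one-off costs of a major and a minor complication are the only inputs
with no published value (the authors cite literature sources without
printing figures). Because the engine is affine in every cost component,
the pair reproducing the two published strategy totals ($13,936.38
operative, $13,413.04 non-operative) solves a 2×2 linear system whose
coefficients — the expected complication event counts per strategy — are
measured by running the engine at unit costs against a zero-cost baseline.
`calibrate_complication_costs()` solves that system and verifies the
round trip to within $0.01.

The solved pair for the base case is approximately **major ≈ +$25,463 and
minor ≈ −$4,117**. The negative minor value is a genuine structural
finding, not a bug: after episode and re-rupture costs, the published
totals leave cost gaps of roughly $797 (operative) and $689 (non-operative)
to be explained by complications, yet the operative arm experiences about
2.7× the minor and 1.6× the major complication events of the non-operative
arm — so no pair of non-negative one-off event costs can close both gaps at
once. The published totals evidently embed cost structure this model cannot
see (for example complication-specific follow-on care or offsets). The
calibration therefore refuses negative solutions by default and accepts
them only with `allow_negative = TRUE`, which `base_case_parameters()` uses
deliberately: the algebraic pair reproduces both published totals exactly,
which is all the downstream threshold and acceptability analyses require.
The solved values are reported as what they are — a numerical bridge — and
must not be quoted as the authors' inputs. One visible artifact: in tornado
rankings the inflated major-complication cost exaggerates the influence of
the operative major-complication rate.

## Comparison metrics

`compare_strategies()` reports incremental cost and QALYs (comparator −
reference, with non-operative management as the reference), classifies the
comparison (`reference_dominates`, `comparator_dominates`, `trade_off`,
`equivalent`), and reports an incremental cost-effectiveness ratio only for
trade-offs — a dominated strategy is labelled as such rather than given a
meaningless negative ratio. Net monetary benefit `λ × QALYs − cost` decides
preference at each willingness-to-pay λ; ties (|ΔNMB| < 1e-9) resolve to
the reference strategy, the less invasive option — an arbitrary but
documented convention. In the calibrated base case the package computes
ΔC = $523.34 and ΔQ ≈ −0.020, i.e. operative repair is dominated.

## Deterministic sensitivity analysis

`one_way_sweep()` grids one parameter with everything else fixed;
`find_threshold()` bisects to the decision flip point (tolerance $0.01 for
money, 1e-4 otherwise) under one of two criteria:

* `cost_parity` — total expected costs equal. The published flip points
  behave as cost parity: $3145 − $523.34 ≈ $2621.66 for the operative
  hospitalization cost (printed $2621) and ≈ $28.87/h for the wage (printed
  $29). An NMB flip at $50,000/QALY with ΔQ ≈ −0.02 would instead give
  ≈ $1622, so `cost_parity` is the default for reproducing the printed
  numbers and both criteria are exposed.
* `nmb_flip` — the net-monetary-benefit ranking at λ flips. Used for the
  proportional non-operative utility decrement, where the package finds
  ≈ 1.8% (printed as 2%): in closed form
  `(ΔC/λ + ΔQ) / QALYs_non-op ≈ (523.34/50000 + 0.020)/1.70`.

One further published flip point — non-operative care requiring about 3.3
more missed-work weeks than surgery — is exercised by sweeping
`episode_costs.non_operative.weeks_missed` under cost parity; the package
finds ≈ 3.0 extra weeks. The residual gap is consistent with the
unavailable details of the authors' indirect-cost handling and is left as a
known limitation rather than forced.

`tornado()` ranks parameters by the swing of the NMB difference across
their plausible ranges. Because the default parameter set keeps the
verbatim operative rates, the default ranges vary `rates_operative.*`
directly over their CI-implied spans (risk-ratio CI × non-operative rate,
clipped so the arm's event mass stays below 0.95).

## Probabilistic sensitivity analysis

`run_psa()` samples every uncertain parameter simultaneously
(`default_psa_spec()`), runs both strategies per draw, and reports
acceptability — the fraction of draws in which each strategy has the
highest NMB — at each willingness-to-pay value. Families follow standard
practice: beta for probabilities, lognormal for risk ratios (log-SD =
CI width on the log scale / 3.92), gamma for costs, truncated normal for
utilities. Spreads come from printed CIs where they exist (risk ratios; the
operative hospitalization cost, SE ≈ $50.77); all remaining spreads are
package defaults, echoed in the spec tibble and in every PSA manifest:
SE = 10% of the mean for costs, 20% of the mean for probabilities, SD 0.05
for utilities.

Three structural choices matter:

* **Shared fees are drawn once.** The surgeon fee shared by primary and
  re-rupture surgery, and the physical-therapy course shared by all
  episodes, are single fee-schedule quantities; each is sampled once and
  written to every location it applies to (the `paths` list-column).
* **Rate uncertainty propagates multiplicatively.** Each operative rate is
  scaled by the sampled-to-base ratios of its risk ratio and of its
  non-operative rate. This keeps the verbatim operative column as the
  center of the sampling distribution and makes a zero-variance PSA
  reproduce the base case exactly, while a literal
  "sampled RR × sampled rate" product would shift the center to the
  derived (inconsistent) column. Rates are clipped to [0, 1] and rescaled
  if an arm's event mass reaches 1; independently sampled recovery
  utilities are sorted to restore monotonicity.
* **The relative utility of the arms is itself sampled.** The base case
  assumes utility parity between arms, but that equality is the model's
  least certain and most influential input — the deterministic analysis
  shows a 2% relative decrement flips the decision. Holding it fixed would
  make the PSA assert certainty about exactly that quantity, and the
  acceptability would sit near 93% and could only *increase* with λ, which
  is qualitatively incompatible with an analysis whose acceptability falls
  from $50,000 to $100,000 per QALY. `utilities.nonoperative_ratio` is
  therefore sampled with the default utility SD (0.05), truncated so
  non-operative utilities stay within [0, 1].

With these defaults and 10,000 draws the package finds non-operative
management cost-effective in roughly 67–68% of draws at $50,000/QALY and
66% at $100,000/QALY (seed-dependent within Monte Carlo error). The
published figures are 71.7% and 69.1%; exact reproduction is impossible
without the authors' unprinted spread parameters, so agreement is expected
only to within several percentage points, and — matching the published
pattern — acceptability decreases with the threshold.

The random-number stream is consumed column-by-column in spec row order
from a single seeded generator, so a given (seed, spec) pair yields
bitwise-identical draws on any platform with IEEE double semantics.

## Scenario generators and what the tests show

`base_case_parameters()` rebuilds the published inputs in code (nothing is
stored on disk, so the fixture cannot drift); `random_scenario()` draws
structurally valid random parameter sets; `degenerate_scenarios()` supplies
edge cases with closed-form answers. The test suite runs the engine over
1,000 random scenarios (occupancy conservation), compares it to the
exhaustive branch-enumeration oracle to 1e-9, and pins the closed forms.
Problem sizes in the default run — 8-cycle horizons, 1,000-scenario
property sweeps, 10,000-draw PSA — were chosen so the whole suite completes
in about a minute while keeping Monte Carlo error on acceptability near
half a percentage point.

These scenarios emulate *parameter-level* variation only. They do not
emulate patient-level heterogeneity, time-varying transition probabilities,
mortality (the model has no death state), or costs beyond the published
component structure — so passing tests demonstrate fidelity to the cohort
model, not validity of that model for any individual patient.

## Known limitations

* The complication event costs are calibrated stand-ins (negative minor
  value; see above), and tornado rankings involving them inherit that
  artifact.
* The published 3.3-week missed-work flip point is reproduced only as
  ≈ 3.0 weeks.
* PSA spreads without printed CIs are package defaults; the acceptability
  fractions are approximate-reproduction targets only.
* Two strategies only; extended dominance and multi-strategy frontiers are
  out of scope, as are discounted analyses beyond the constant-rate hook in
  `run_settings()` and half-cycle corrections (the published model uses
  neither).
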