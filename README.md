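# tendocea

Cost-utility analysis of operative versus non-operative management of acute
Achilles tendon rupture.

## What this package is for

Acute Achilles tendon rupture is the most common tendon injury of the lower
limb, and whether to repair it surgically is contested: surgery lowers the
re-rupture rate but costs more and carries higher complication risk, while
functional non-operative care (early weight bearing in a brace) keeps
patients off work longer. `tendocea` implements a Markov cohort
cost-utility model that weighs these trade-offs from the societal
perspective — direct medical costs plus missed-work costs, in 2014 US
dollars — for health economists, orthopaedic researchers and students of
decision-analytic modelling.

The cohort moves through mutually exclusive health states (recovering, full
benefit, minor complication, major complication) over eight 3-month cycles
(2-year horizon). An episode resolves one cycle after treatment with
probabilities *p* = (p_rerupture, p_major, p_minor) per arm; re-ruptured
patients always undergo surgery, restarting the recovery utility clock and
re-entering the lottery with operative probabilities. Effectiveness is
measured in quality-adjusted life years with time-dependent utilities
(0.7 → 0.8 → 0.9 by cycle since treatment; minor complications ×0.9, major
×0.8). Strategies are compared by incremental cost ΔC, incremental
effectiveness ΔE, the incremental cost-effectiveness ratio
ICER = ΔC/ΔE (with dominance classification when sign patterns make the
ratio meaningless), and net monetary benefit NMB(λ) = λ·E − C at
willingness-to-pay λ. Deterministic sensitivity analysis bisects single
parameters to their decision flip points; probabilistic sensitivity
analysis samples all parameters jointly (beta rates, lognormal risk
ratios, gamma costs, truncated-normal utilities) and traces
cost-effectiveness acceptability curves.

## Worked example

```r
library(tendocea)

p <- base_case_parameters()   # published inputs, complication costs calibrated
out <- run_strategies(p)
compare_strategies(out$non_operative, out$operative)
#> <ats_comparison>
#>   non_operative  $13413.04  1.70 QALYs
#>   operative      $13936.38  1.68 QALYs
#>   incremental (comparator - reference): $523.34, -0.02 QALYs
#>   Dominated (non_operative dominates)
#>   at $50,000/QALY: NMB difference $-1500.12, preferred = non_operative
#>   at $1e+05/QALY: NMB difference $-2476.90, preferred = non_operative
```

Non-operative management costs $523.34 less and yields ≈0.02 more QALYs
over two years, so it *dominates* operative repair — no ICER is defined,
and at both conventional thresholds the NMB difference favours
non-operative care. The margins are small, and single parameters can flip
the decision:

```r
find_threshold(p, "episode_costs.operative.hospitalization", bounds = c(0, 3145))
#>   parameter                               criterion    wtp  threshold ...
#> 1 episode_costs.operative.hospitalization cost_parity 50000     2622.
```

If operative hospitalization falls below ≈$2,622 (from $3,145), surgery
becomes the cheaper strategy. Analogous calls flip the decision at an
hourly wage above ≈$29 (`wage.hourly_wage`) or a ≈2% relative utility
decrement for non-operative care (`utilities.nonoperative_ratio`, criterion
`"nmb_flip"`). For joint uncertainty:

```r
psa <- run_psa(p, n = 10000, seed = 1)
psa$acceptability
#> # A tibble: 2 × 3
#>      wtp fraction_nonoperative fraction_operative
#> 1  50000                 0.678              0.322
#> 2 100000                 0.656              0.344
```

With the package's documented default spreads, non-operative care is the
cost-effective strategy in roughly two-thirds of draws; the published
analysis reports 71.7% at $50,000/QALY, and exact reproduction is not
possible because the spread parameters behind that figure are not printed —
agreement is expected only to within several percentage points (see the
methods vignette). `plot_ceac(psa)`, `autoplot(psa)` and `plot_tornado()`
draw the standard figures; `report_base_case()`, `report_dsa()` and
`report_psa()` write CSV/JSON artifacts with a manifest, and
`inst/cli/tendocea.R` wraps them for shell use.

A caveat worth knowing before quoting numbers: the per-event complication
costs are not published, so the package calibrates them to the published
strategy totals; the exact solution contains a negative minor-complication
offset, a structural finding documented in the methods vignette.

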