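# cuatree

Decision-tree cost-utility analysis of statin dose-escalation strategies.

## The problem

Choosing a first-line statin for dyslipidemia is, in resource-constrained
health systems, as much a budget question as a clinical one. `cuatree` is
for health-economics analysts who need a small, fully tested engine for
the standard two-stage treatment pathway: start a statin at a low dose,
reassess LDL-C at 8 weeks, double the dose for patients who missed the
target, and follow the cohort over a multi-year horizon. The package
evaluates each strategy's costs and quality-adjusted life years (QALYs),
compares strategies by incremental cost-effectiveness ratio (ICER) with
dominance and willingness-to-pay (WTP) classification, and quantifies
parameter influence with one-way deterministic sensitivity analysis.

It ships a complete Vietnam 2024 scenario comparing pitavastatin 2/4 mg,
atorvastatin 10/20 mg and rosuvastatin 5/10 mg at official drug-tender
prices over a 14-year horizon.

## The model

With $p_1, p_2$ the LDL-C target-attainment probabilities on the initial
and escalated dose, the tree's three terminal branches have probabilities
$p_1$, $(1-p_1)p_2$ and $(1-p_1)(1-p_2)$. Each branch accrues drug and
monitoring costs (daily price × days on each dose, plus lipid panels) and
a utility contribution (utility weight × branch probability; `u_base` for
target-achievers, `u_fail` for the never-controlled state). Then, per
strategy and per comparison:

- expected cost $= \sum_b P(b)\,C(b)$,
- $\mathrm{QALY} = \mathrm{utility} \times \mathrm{LYG}$ (optionally
  annuity-discounted),
- $\mathrm{ICER} = (\mathrm{Cost}_A - \mathrm{Cost}_B) /
  (\mathrm{QALY}_A - \mathrm{QALY}_B)$,

banded against WTP thresholds at 1× and 3× GDP per capita. Because the
fail-state utility is not directly observable, `calibrate_fail_utility()`
solves for it in closed form from one reported strategy total — the total
is linear in `u_fail` — and the same value then predicts the remaining
strategies' totals to ~1e-8, validating the reconstruction.

## Worked example

```r
library(cuatree)
cfg <- builtin_scenario("vietnam_dyslipidemia_2024")

evaluate_strategy("pitavastatin", cfg)
#> <cua_strategy_result> pitavastatin
#>             branch probability     cost utility_contribution
#>    ACHIEVE_INITIAL    0.717000 69203400           0.59188350
#>  ACHIEVE_ESCALATED    0.225268 94582600           0.18595873
#>               FAIL    0.057732 94582600           0.04086848
#>   overall attainment 0.9423 | expected cost 76,385,713.6 | utility 0.81871071 | QALY 11.46195000
```

Reading this: 71.7% of patients reach target on pitavastatin 2 mg at a
14-year cost of VND 69.2 million (drug + 2 lipid panels); the 28.3% who
escalate to 4 mg cost VND 94.6 million each (extra panel, dearer dose),
and 79.6% of them reach target, for 94.23% overall attainment. Weighting
branches by probability gives the expected cost and the total utility
0.8187 (between `u_fail` = 0.7079 and `u_base` = 0.8255).

Comparisons against the scenario's reported lifetime totals (which add
downstream cost components to the tree's drug/monitoring costs):

```r
compare_strategies(cfg, "pitavastatin", "atorvastatin",
                   totals_override = builtin_reference_totals())
#> <cua_comparison> pitavastatin vs atorvastatin [paper_compatible]
#>   delta cost -31,280,140 | delta QALY -0.16007988
#>   ICER 195,403,320 per QALY
#>   SW / none / cost_effective
#>   SW quadrant: cost effective

compare_strategies(cfg, "pitavastatin", "rosuvastatin",
                   totals_override = builtin_reference_totals())
#> <cua_comparison> pitavastatin vs rosuvastatin [paper_compatible]
#>   delta cost 89,247,958 | delta QALY -0.07184857
#>   ICER -1,242,167,492 per QALY
#>   NW / comparator_dominant / dominance_verdict
#>   intervention dominated by comparator
```

Pitavastatin saves VND 31.3 million versus atorvastatin at a small QALY
loss — about VND 195 million saved per QALY forgone, inside the 1–3× GDP
band (VND 114–342 million) — but is dominated by rosuvastatin (costlier
*and* less effective, the NW quadrant). The default `paper_compatible`
banding reads SW-quadrant ICERs on the conventional scale; a
`quadrant_aware` mode with the inverted SW rule is available (see the
vignette).

## The analysis workflow

Numbered drivers under `analysis/` rerun the full study and write tables
and charts to `results/`:

1. `01_strategy_costs_utilities.R` — per-strategy branch costs, expected
   costs, utilities, QALYs, attainment.
2. `02_incremental_analysis.R` — pairwise ICERs on tree-computed and on
   reported lifetime totals; WTP bands; the pitavastatin threshold price.
3. `03_sensitivity_tornado.R` — ±20% one-way sensitivity analysis and
   tornado diagrams for both comparisons.
4. `04_synthetic_validation.R` — engine validation on 500 seeded random
   scenarios (calibration recovery, quadrant coverage).

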