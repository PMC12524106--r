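---
title: "A decision-tree cost-utility model for statin dose escalation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-utility model for statin dose escalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuatree)
```

## The model

`cuatree` implements a two-stage decision tree for lipid-lowering therapy
with dose escalation. A statin-naive cohort starts on an initial dose; at a
reassessment visit (day 56, i.e. 8 weeks, by default) LDL-C target
attainment is checked, and patients who missed the target switch to an
escalated dose — typically double the initial one — for the rest of the
horizon. Three terminal branches result:

* `ACHIEVE_INITIAL`, probability $p_1$;
* `ACHIEVE_ESCALATED`, probability $(1 - p_1)\,p_2$;
* `FAIL`, probability $(1 - p_1)(1 - p_2)$,

where $p_1$ and $p_2$ are the attainment probabilities on the two doses.
The branch probabilities sum to one by construction, and the overall
attainment rate is $p_1 + (1 - p_1)p_2$. Target attainment, once reached,
is assumed permanent — the model tracks lipid control, not downstream
cardiovascular events (a deliberate scope choice; see *Limitations*).

Each branch carries a cost and a utility contribution:

* **Cost.** The no-escalation branch accrues the initial dose's daily
  price over the whole horizon plus two four-test lipid panels. Both
  escalation branches accrue the initial price up to the escalation day,
  the escalated price afterwards, and three panels. Patients who escalate
  stay on the escalated dose whether or not it works, so the two
  escalation branches share one drug/monitoring cost; only optional
  per-branch `downstream_branch_costs` can separate them. Expected cost is
  the probability-weighted branch cost.
* **Utility.** Target-achievers carry the base utility weight `u_base`;
  the never-controlled branch carries `u_fail`. Each branch contributes
  *weight × probability*, and the strategy total — a convex combination
  between `u_fail` and `u_base` — converts to QALYs as
  $\mathrm{QALY} = \mathrm{utility} \times \mathrm{LYG}$.

The packaged Vietnam 2024 scenario fixes the horizon at 14 life-years
gained (cohort mean age 61 to life expectancy 75) with 365-day years, and
compares pitavastatin 2/4 mg, atorvastatin 10/20 mg and rosuvastatin
5/10 mg at 2024 drug-tender prices, with every laboratory test at
VND 27,300.

```{r fixture}
cfg <- builtin_scenario("vietnam_dyslipidemia_2024")
strategy_table(evaluate_scenario(cfg))
```

## Discounting: why the default is `none`

The scenario declares a 3% annual discount rate, and the engine supports
it (`discount_mode = "annual_annuity"` multiplies utilities by the present
value of an annual annuity, $\sum_{t=1}^{H}(1+r)^{-t}$). The default mode
is nevertheless `none`: the published per-dose cost totals this scenario
reproduces are exactly undiscounted drug-day sums (e.g. pitavastatin 2 mg:
$13{,}500 \times 14 \times 365 + 2 \times 4 \times 27{,}300 =
69{,}203{,}400$), and the published QALY totals are not consistent with a
3% annuity either. Reproduction therefore runs undiscounted, and the
annuity mode is available for methodologically standard analyses. The
annuity converges to the undiscounted horizon as $r \to 0$, which the test
suite checks.

For the same reason the engine does not attempt to reproduce the published
*absolute* lifetime totals (total cost ≈ VND 1.06–1.09 billion per
strategy, QALY ≈ 11.1–11.3): those include downstream components —
lifetime complication costs and age-stratified utility adjustments — whose
internals are not part of the published inputs. They enter the package as
an opaque totals override (`builtin_reference_totals()`), so the
incremental layer can run on them unchanged, and as optional
`downstream_branch_costs` in the scenario schema.

## Calibrating the fail-state utility

Only the age-band base utility (0.8255) is recoverable from the published
inputs; the utility of the never-controlled state is not stated directly.
But the strategy total utility is *linear* in `u_fail`, so one reported
strategy total identifies it in closed form:

$$u_{\text{fail}} \;=\; \frac{\text{total} - u_{\text{base}}\,[p_1 + (1-p_1)p_2]}{(1-p_1)(1-p_2)}.$$

Calibrating from the atorvastatin total (0.82070086) gives
$u_{\text{fail}} \approx 0.70790$, and that single value then predicts the
other two strategy totals to within $10^{-8}$ — a strong consistency check
on the reconstruction. The packaged fixture stores the calibrated value to
8 decimals.

```{r calibration}
u_fail <- calibrate_scenario(cfg, "atorvastatin", 0.82070086)
u_fail
strategy_utility(cfg$strategies$rosuvastatin, cfg)$total  # predicts 0.81983168
```

An alternative mixture decomposition
(`compose_fail_utility()`) expresses `u_fail` as
$(1-p_c)\,u_{\text{base}} + p_c\,u_{\text{complication}}$ with the
complication probability $p_c = 0.145$ carried by the scenario. The
complication utility implied by the calibrated `u_fail` (~0.015) is
clinically implausible for a mixture over survivors, which suggests the
original downstream utility structure is more elaborate than a one-step
mixture; `u_fail` is therefore the primary parameter and the composition
is an optional convenience.

## ICERs, dominance and willingness-to-pay bands

`compare_strategies()` forms $\Delta C$ and $\Delta Q$ (intervention minus
comparator), the ICER $\Delta C / \Delta Q$, the cost-effectiveness plane
quadrant, dominance, and a WTP band anchored at GDP per capita
(VND 114,000,000 here): ICERs up to 1× GDP are *very cost-effective*, up
to 3× GDP (VND 342,000,000) *cost-effective*, beyond that *not
cost-effective*. Boundary ties are resolved downwards (exactly 1× GDP is
very cost-effective; exactly 3× is cost-effective) — a stated, testable
convention.

Two classification modes ship because banding is quadrant-dependent in
principle but not always in practice:

* `paper_compatible` (default) bands the raw ICER against the cutpoints in
  both the NE and SW quadrants. This is the convention the packaged
  scenario's source analysis used: its pitavastatin-vs-atorvastatin
  comparison sits in the SW quadrant (cheaper, fewer QALYs) with ICER
  ≈ VND 195.4 million/QALY and is called cost-effective on the NE scale.
* `quadrant_aware` applies the standard decision-theoretic reading: in SW
  the ICER is savings per QALY forgone, so *larger* is better and the band
  ordering inverts (acceptable iff ICER ≥ threshold).

A zero QALY difference is reported as cost-minimisation (cheaper wins)
rather than an infinite ICER, and a zero in either delta maps to a weak
dominance verdict, so every sign combination has exactly one defined
outcome. `icer()` itself signals `cua_undefined_icer` instead of dividing
by zero.

`threshold_price()` exploits the affine dependence of expected cost on any
daily price to solve, in closed form, for the price at which a
comparison's ICER crosses a target threshold; a bisection solver over
$[0, 10 \times \text{current price}]$ cross-checks it to 1 VND.

## One-way sensitivity analysis

`one_way()` perturbs one parameter at a time by ±20% (multiplicatively —
the natural scale for prices, and adopted for probabilities and utilities
as well, with clamping back into valid ranges), recomputes both strategies
and the ICER, and returns base/low/high ICERs, percent changes and the
swing range per parameter; `tornado_order()` sorts by swing and
`render_tornado()` draws the paired-bar chart (orange = parameter
decreased, blue = increased, bars anchored at the base ICER).

Numerical conventions worth stating:

* Percent change is $(\text{perturbed} - \text{base}) / |\text{base}|
  \times 100$, so the sign is meaningful when the base ICER is negative.
* Clamping can collapse `u_base` onto `u_fail`, making both strategies'
  utilities equal; the QALY difference then vanishes up to floating-point
  residue. Differences below $10^{-9}$ QALYs are flagged as undefined
  (`NA`) rather than converted into an astronomically large ratio.
* A perturbation factor of exactly 1 reproduces the base ICER
  bit-for-bit, and `one_way()` never mutates its input scenario.

On the packaged scenario the base pitavastatin-vs-atorvastatin comparison
lies in the SW quadrant, so *cutting* the pitavastatin 2 mg price deepens
the saving and raises the savings-per-QALY ratio, while *raising* it
erodes the saving past zero and flips the ICER negative — a swing of about
±187% of the base value, making the pitavastatin price the dominant lever,
with utilities close behind. Test costs barely move the ICER.

## The synthetic-scenario generator

`random_scenario()` draws structurally valid scenarios — two-arm
strategies with positive prices, probabilities in the unit interval,
`u_fail ≤ u_base` — from ranges that bracket the Vietnam values by a
factor of 0.5–2, which keeps synthetic tests in a regime a health
economist would call realistic for daily statin prices and attainment
rates. Flags enforce (or relax) dose-monotone pricing and
escalated-dose-at-least-as-effective draws; relaxing both lets the
generator reach all four cost-effectiveness quadrants, which the test
suite verifies. Each call seeds its own RNG locally (global random state
is untouched), and `generator_spec_from_scenario()` collapses every range
to a point so the generator reproduces a given scenario exactly.

What the generator emulates is the *structure* of the study inputs, not
their epidemiology: draws are independent and uniform, so it does not
model correlation between a drug's price and its efficacy, adherence
decay, or sampling uncertainty in published probabilities (no confidence
intervals are available for most inputs). Passing tests on synthetic
scenarios therefore demonstrate algebraic and logical correctness of the
engine — probability conservation, cost bounds, calibration
identifiability, dominance exhaustiveness — not real-world validity of any
particular parameterisation.

## Problem sizes and runtime

Everything here is desk-scale. The test suite evaluates the three-strategy
Vietnam scenario exactly, sweeps a 11×11 probability grid, runs 1,000
seeded calibration round-trips (recovery to $10^{-9}$), 1,000 generator
validity draws and a 200-draw quadrant-coverage check, and completes in
well under a minute on one CPU; the analysis scripts use 500 synthetic
draws for the standalone validation step.

## Limitations

* No cardiovascular event simulation and no Markov cycling: lipid control
  is the sole effectiveness endpoint, and attainment is assumed permanent
  over the horizon. Lifetime QALYs are accordingly optimistic.
* The branch-cost structure (full-horizon dosing, 2-vs-3 panels) is a
  reconstruction validated against six published per-dose totals; all its
  constants are config-exposed rather than hard-coded.
* Downstream cost/utility components are opaque: the engine carries them
  as reported totals or per-branch constants, and the published tornado
  percentages that depend on their internals are out of reach (the
  machinery that would produce them is fully implemented).
* Single currency arithmetic (integer VND); the USD rate in the fixture is
  display-only.
* No probabilistic sensitivity analysis or acceptability curves — the
  deterministic one-way analysis is the only uncertainty tool provided.
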