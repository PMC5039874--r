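---
title: "A Markov cohort cost-utility model for trimetazidine add-on therapy in chronic stable angina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for trimetazidine add-on therapy in chronic stable angina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anginacua)
```

## The decision problem

Chronic stable angina patients who remain symptomatic on first-line
anti-anginal therapy (beta-blockers, nitrates, calcium-channel antagonists)
can receive trimetazidine (TMZ) as an add-on to standard of care (SoC). The
add-on relieves symptoms but costs money; the question for a third-party
payer is whether the extra spend buys enough extra health. `anginacua`
answers it with a cost-utility model: both strategies are pushed through the
same disease model, costs and quality-adjusted life-years (QALYs) are
accrued, and the comparison is summarized as an incremental
cost-effectiveness ratio (ICER, EUR per QALY gained) judged against a
willingness-to-pay (WTP) benchmark of 34,000 EUR/QALY (about twice the Greek
GDP per capita).

## Model structure

The disease model is a Markov cohort model with five states: four living
states graded by angina-episode frequency — *minimal* (less than weekly),
*mild* (weekly), *moderate* (several times a week), *severe* (several times
a day) — plus absorbing *death*. Cycles are 3 months; the horizon is one
year (4 cycles), so nothing is discounted (the hook exists and is the
identity at rate 0).

Three conventions fix the arithmetic, and all three are load-bearing for
reproducing the source evaluation:

* **Occupancy is counted at cycle start**, and all rewards (utilities,
  state costs, drug costs) accrue on start-of-cycle occupancy times the full
  cycle length. No half-cycle correction is applied.
* **Death acts at cycle end on the state occupied during the cycle.** The
  state-dependent annual death probabilities are converted to 3-month
  probabilities by the constant-rate formula
  `p_cycle = 1 - exp(log(1 - p_annual)/4)`, and are identical across
  strategies.
* **Angina transitions happen once, at the end of cycle 1.** The efficacy
  evidence covers a 3-month follow-up; in its absence beyond that window,
  survivors keep their cycle-2 state until death or the end of the horizon.
  Within cycle 1 the ordering is: survivors of the cycle transition, i.e.
  the cycle-1 death toll is taken from the baseline states.

These choices are the only combination, among the natural candidates we
enumerated (death before/after the transition, rewards at cycle start, end
or midpoint, linear or constant-rate probability conversion), that
reproduces the published per-arm life-years, QALYs and costs
simultaneously.

## Parameters, and why the fixture stores fractions

`angina_parameters()` ships the complete input set: per-strategy 4x4
first-cycle transition matrices, annual mortality by state
(4.6/4.8/8.1/10.9%), the baseline distribution of the symptomatic cohort
(0/47/26/27%), utilities (0.81/0.75/0.60/0.39), five state-dependent annual
cost categories (outpatient visits, diagnostic tests, laboratory tests,
hospitalization without and with revascularization), and net monthly drug
costs of 29.18 EUR (TMZ+SoC) versus 23.40 EUR (SoC), all in EUR 2016.

The published transition tables print percentages with two decimals. Every
one of those percentages is exactly the rounding of a trial fraction, and
the row denominators are recoverable from the roundings: 262/184/103/105
patients per origin state in the TMZ arm and 181/191/89/128 in the
comparator arm, with the baseline distribution equal to the TMZ arm's
symptomatic state counts (184, 103, 105)/392. The fixture therefore stores
the exact fractions (and carries the denominators as a `row_ess`
attribute). This matters quantitatively: with the 2-decimal roundings as
inputs, the incremental cost comes out near 4.06 EUR and the ICER near 460
EUR/QALY, several tolerance widths away from the published 3.82 EUR and
430.67 EUR/QALY; with the fractions, every published figure is reproduced
to its printed precision:

```{r base-case}
params <- angina_parameters()
base_case(params)
```

The configuration schema (JSON, probabilities as fractions) is documented
in `read_parameters()`; the fixture is also shipped as a config file at
`angina_config_path()`. Rows that sum to within 0.5% of 1 — printed
rounding — are renormalized proportionally; anything further off is
rejected, as are percent-style values above 1 in probability fields.

## One-way sensitivity analysis

`run_owsa()` varies clinical inputs by ±10% and cost inputs by ±20% around
the base case, one at a time, and ranks parameters as a tornado. Two
conventions deserve explanation:

* **Transition rows are rebalanced against the stay-in-state cell.** A
  transition row has three independent off-diagonal probabilities; the
  stay-in-state probability is the residual completing the row to 1 (which
  is also how a spreadsheet model parameterizes a row). Varying a cell
  therefore trades mass against the residual cell only. The alternative —
  rescaling all complementary cells proportionally — is available through
  `perturb_parameter(..., balance = "proportional")` and remains the
  default of that function, but it dilutes each cell's effect across the
  whole row and does not reproduce the source evaluation's ranking.
  Stay-in-state cells, being residuals, are not independent handles.
* **Bars live on the signed cost-per-QALY scale.** An endpoint where the
  add-on dominates (cheaper and more effective) has a well-defined negative
  ratio, so dominance widens a bar instead of breaking it. Only if an
  endpoint reversed the sign of the QALY difference would the ranking fall
  back to the incremental-net-benefit range at the WTP, keeping the order
  always defined.
* **Drug acquisition costs are not tornado handles by default.** They are
  administered prices, held fixed in the PSA for the same reason; their
  what-if lives in the dedicated `rebate_scenario()` analysis, which
  reduces both strategies' net monthly costs by a volume-rebate fraction.
  Passing `drug_costs = TRUE` to `parameter_handles()` re-includes them.

Under these conventions the three most influential parameters are the
TMZ-arm moderate-to-mild transition probability, followed by the
comparator's severe-to-mild and moderate-to-mild probabilities, and every
endpoint stays far below the 34,000 EUR/QALY threshold. A 2% volume rebate
lowers the ICER to about 273 EUR/QALY; at 12% the add-on strategy dominates.

## Probabilistic sensitivity analysis

`assign_distributions()` attaches the standard second-order families:
gamma for every state-cost cell (costs are non-negative and right-skewed),
beta for utilities and annual mortality, one Dirichlet per transition row.
Drug acquisition costs stay fixed. The source evaluation names these
families but no variances, so the spreads are explicit tunables of
`uncertainty_spec()`:

* `cost_cv = 0.102` — a coefficient of variation that makes the 95% range
  of each gamma roughly ±20% of its mean, mirroring the one-way cost range;
* `utility_ess = mortality_ess = 100` — beta effective sample sizes
  (method of moments, `alpha = mean * ess`);
* `transition_ess = 100` — Dirichlet concentration per row, with
  `transition_ess = "row_ess"` substituting the observed per-row trial
  denominators recovered above (89–262), the evidence-based choice.

Each of 5000 iterations draws one coherent parameter set (fixed draw order:
costs, utilities, mortality, then the two strategies' transition rows),
re-runs the deterministic engine for both strategies and records the
incremental cost and QALY pair; decisions use net monetary benefit, and
per-draw ICERs are never averaged. The acceptability curve (`ceac()`)
reports the fraction of draws with positive incremental net benefit across
the WTP axis. At 34,000 EUR/QALY the probability that the add-on is
cost-effective is about 0.86 under the generic effective sample size and
about 0.89 with the observed row denominators; since the published 89% was
computed under unreported variances, we read it as indicative and treat
only the structural properties (degenerate variances collapse to the
deterministic result; the curve is monotone when every draw shows a QALY
gain; identical seeds reproduce identical results) as hard requirements.

## Validation against an independent oracle

Because the engine is only a handful of matrix recursions, the package
carries its own cross-check: `microsimulate()` pushes individual patients
through the same event ordering, reusing the engine's per-cycle transition
*probabilities* but not its trace recursion, and returns empirical
occupancies and per-patient accruals with Monte-Carlo standard errors.
Initial states are allocated deterministically (largest-remainder quota),
so initialization adds no noise and a degenerate model (identity
transitions, zero mortality) reproduces the cohort trace exactly.

`synthetic_parameters()` generates random but structurally valid parameter
sets — row-stochastic transitions with a pull toward persistence, mortality
rising and utility falling with severity, costs rising with severity, a
symptomatic baseline — for property-based testing. The oracle-equivalence
test runs 20 such sets at 50,000 patients per arm and compares every
occupancy cell and accrued quantity at 3 Monte-Carlo standard errors.
Among the ~2,400 simultaneous comparisons this induces, a correct
implementation is still expected to exceed 3 SE in a fraction of cells by
chance (about 0.27%); the test therefore allows at most a 0.5% share of
cells beyond 3 SE and none beyond 4.5 SE, which keeps its family-wise
false-alarm rate under 1% without loosening the per-cell criterion. These
problem sizes keep the whole validation under a minute while leaving the
standard errors small enough to catch accounting errors of the size the
conventions above protect against.

What the synthetic generator does *not* emulate: correlations between cost
categories, patient-level cost heterogeneity within a state, age-dependent
background mortality, or horizons beyond what `n_cycles` expresses. Passing
tests certify the cohort arithmetic and accounting, not the external
validity of any particular parameter set.

## Numerical choices and edge cases

* Transition rows are renormalized on construction and checked to 1e-9
  thereafter; traces are conserved to the same tolerance.
* `annual_to_cycle_probability(1)` is an error (the rate is undefined);
  probabilities are validated as fractions, and loaders reject values
  above 1 in probability fields to catch percent/fraction mix-ups.
* The ICER is computed from unrounded totals and only for genuine
  trade-offs; dominance and equality are explicit classifications, never a
  division by zero. Ties in tornado spreads break by handle id.
* A perturbation that cannot keep a row stochastic is an error in
  `perturb_parameter()`; inside the tornado, infeasible relative increases
  are clamped to the feasible boundary instead, so the bar ends exactly
  where the parameter space does.
* A gamma cost with base value 0 stays a point mass at 0; infinite
  effective sample sizes collapse beta/Dirichlet families to their means.

## Limitations

The model inherits the source evaluation's scope: a 1-year horizon (no
long-term efficacy evidence for the add-on), treatment effect confined to
the first cycle, strategy-independent mortality, no tunnel states, no
indirect or out-of-pocket costs, and prices as administered net costs
(rebate scenarios rather than price modelling). The recovered trial
denominators rest on the printed tables being exact roundings of
fractions; they reproduce every printed percentage, but the original
patient-level data were not available to confirm them directly.
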