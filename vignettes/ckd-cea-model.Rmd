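---
title: "The ckdcea cohort model: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ckdcea cohort model: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdcea)
```

`ckdcea` implements a cohort-level Markov decision model comparing add-on
cardiorenal therapy (finerenone, an SGLT2 inhibitor, or both) against
standard of care (SoC) in chronic kidney disease with type 2 diabetes, from
a Chinese healthcare-system perspective. This vignette is the package's own
account of the model: its structure, the conventions chosen where a
published description is silent, and what the tests do and do not establish.

## State space and dynamics

The cohort occupies 17 compartments: eight alive health states — CKD stages
1/2, 3, 4, stage 5 without renal replacement therapy (RRT), and acute and
post-acute phases of dialysis and kidney transplantation — each split by
cardiovascular (CV) event history (*no-CV* / *post-CV*), plus absorbing
death. Acute dialysis and acute transplant are tunnel states: their
transition rows move all survivors to the post-acute phase after one cycle,
which is what lets a one-off acute cost be charged as that cycle's state
cost. The cycle length is 4 months (1/3 year), the assessment interval of
the underlying outcome trials; the base-case horizon is 10 years
(30 cycles) and the scenario horizon 4 years (12 cycles).

The SoC transition matrix governs **survivors only**; its printed rows
already sum to 100% with no death column. All-cause death is therefore a
separate competing per-cycle risk by state (dialysis states share one risk,
transplant states another), applied before the state transition.

### Within-cycle event order

A published cohort model rarely states its within-cycle ordering, yet the
trace depends on it. `ckdcea` fixes, documents, and tests this order:

1. **Death** removes `p_death(state)` from every compartment.
2. **First CV events** strike no-CV survivors at their *origin* state's
   per-cycle risk. (An occupant of CKD 3 faces the CKD 3 risk this cycle
   regardless of where it transitions; the alternative — destination-state
   risk — is indistinguishable in aggregate outputs but changes individual
   products, and the origin convention makes single-compartment traces
   hand-checkable: from a pure CKD 3 cohort, first events are
   `0.9942 × 0.0095` of the cohort.)
3. **State transition** among the alive states, identical for both CV
   layers; incident first-CV cases land in the post-CV layer of their
   destination state, an irreversible switch. Subsequent CV events are
   tallied for pre-existing post-CV survivors at a flat per-cycle risk
   (8.5%), with no layer or state change and no strategy adjustment (no
   relative effect is published for it).
4. **Adverse events** (hyperkalemia hospitalization, acute kidney injury,
   discontinuation) accrue as survivor occupancy × per-cycle risk. They are
   cost/disutility modifiers only and never move occupancy; the
   discontinuation tally likewise has no structural effect by default, as
   no consequence for it is published.

## Treatment effects

All relative effects act on the **rate scale**:
`p' = 1 − (1 − p)^ratio`, i.e. the underlying constant hazard is multiplied
by the ratio and converted back. This is standard decision-model practice
and keeps probabilities in [0, 1] for any positive ratio, where naive
multiplication would not. The conversions `r = −ln(1 − P)/t` and
`P = 1 − e^{−rt}` are exposed as `prob_to_rate()` / `rate_to_prob()` and
round-trip to 1e−12.

Per strategy, relative to SoC:

* the **relative eGFR-decline rate** scales progression among CKD stages
  1/2–4 (1/2→3, 1/2→4, 3→4) — it is the only quantitative slope parameter
  available, so "slower eGFR decline" is operationalized as proportionally
  slower stage-progression hazards;
* the **renal-composite HR** scales entries into late-stage renal events
  (CKD 5 without RRT, acute dialysis, acute transplant) from the CKD 3,
  CKD 4 and CKD 5 rows. CKD 3 is included because its printed row feeds
  dialysis and transplant directly; the regression transition CKD 5→CKD 4
  is deliberately left unadjusted;
* the **first-CV HR** and **mortality HR** scale the respective per-cycle
  risks in every state.

After each matrix adjustment the stay probability absorbs the difference,
so rows re-sum to 1; the two matrix operations touch disjoint off-diagonal
entries and therefore commute (tested). A sampled ratio large enough to push
a stay probability negative raises an infeasibility error, which the PSA
catches and redraws.

## Economic valuation

Costs (2023 CNY) and QALYs accrue per cycle and are discounted at 5% per
year with the factor `(1.05)^(−k/3)` at cycle `k`; QALYs use the same
factor as costs. Conventions:

* **State accrual** uses end-of-cycle occupancy; with
  `half_cycle_correction = TRUE` it uses the mean of start- and
  end-of-cycle occupancy. The correction is off by default — the analysis
  this package reproduces does not mention it — but it is a first-class
  setting because it shifts totals by roughly half a cycle's accrual.
* **Drug costs.** SoC drug cost (1,561 CNY/cycle) applies in every alive
  state in every arm. Finerenone (1,445) and/or SGLT2i (494) apply in
  pre-RRT states only, by default, consistent with label restrictions in
  kidney failure; `drug_continue_rrt = TRUE` continues them through
  dialysis/transplant. Both flags are part of the documented configuration
  sweep in the acceptance tests.
* **Composite CV event.** The four event types (MI, ischemic stroke,
  hemorrhagic stroke, HF hospitalization) collapse to one composite via
  mix weights: acute cost and acute disutility per incident event (first
  and subsequent) for exactly one cycle; post-acute cost and disutility
  per post-CV occupant every cycle **from the cycle after the event** —
  incident cases are excluded from that cycle's post-acute accrual so the
  acute and ongoing phases never double-count. Both stroke types share the
  stroke disutility.
* **One-off costs.** Death cost (36,487 CNY) per incident death; acute
  dialysis/transplant costs via their tunnel-state occupancy.
* **Clamping.** State utility plus the post-acute decrement is clamped at
  0 per compartment, and a cycle's net QALY accrual at 0, so QALYs are
  never negative.

Incremental results report `NMB = ΔQALY × WTP − ΔCost` at
WTP = 268,074 CNY/QALY (3× 2023 GDP per capita), with dominance labelled
when cost saving and QALY gain coincide; the ICER is reported only when
defined (no dominance, |ΔQALY| ≥ 1e−12).

## Baseline distribution and CV event mix

Two inputs of the published analysis live in supplementary material that is
not reproduced in the packaged tables: the baseline CKD-stage distribution
and the CV event-type mix. `reference_parameters()` substitutes documented
package defaults — 15% / 60% / 25% across CKD 1/2, 3, 4, and equal ¼
weights across the four CV event types — and warns so no user mistakes them
for published values. Both are plain arguments (and config keys), and every
qualitative conclusion the tests assert (dominance of triple therapy, NMB
sign, PSA dominance probability) holds across the baseline variations we
probe. Absolute cost and QALY totals, and the tornado ordering, do move
with these inputs, which is exactly why they are surfaced rather than
buried.

## Sensitivity analysis

**One-way (tornado).** Each of the 71 ranged parameters is set to its low
and high bound in turn — everything else at base case — and both arms are
re-run; entries are ranked by NMB swing. Grouped rows (the shared dialysis
mortality, for instance) move as one scalar, as printed.

**Distribution fitting.** Each (low, high) range is read as a 95% interval,
`s = (high − low)/3.92`, and the printed family is fitted by method of
moments around the base case: beta via
`α = m(m(1−m)/s² − 1)`, gamma via `shape = m²/s², scale = s²/m`, lognormal
by matching mean and sd on the natural scale (a CI-on-log-scale option
exists for hazard ratios). Negative disutilities, printed with beta
families, are fitted on their magnitude and drawn with the sign restored.
Degenerate ranges collapse to a point mass; an infeasible beta
(s² ≥ m(1−m)) falls back to uniform(low, high) with a warning. Fitted
means equal the base case by construction (verified by simulation at
n = 10,000 within 3 Monte-Carlo standard errors).

**Probabilistic.** Each of the 1,000 iterations draws every ranged
parameter independently (no correlation structure is published), rebuilds
all strategy models, and runs the full model; results are reproducible
bitwise under a fixed seed. The acceptability curve reports the fraction of
draws with positive NMB over a WTP grid, and `psa_dominance()` the fraction
of draws that are simultaneously cost-saving and QALY-gaining.

## The synthetic generator

`random_parameter_set()` emulates the *statistical shape* of the inputs the
model consumes — a row-stochastic progression matrix honouring the
structural zeros of the published layout (tunnel rows, no return from
transplant), per-cycle risks well below 1, utilities in [0.5, 1], effect
ratios near 1, positive costs, simplex baseline shares and event mixes —
not any patient-level data. It exists so that every pipeline stage can be
property-tested end to end on fresh inputs (25 seeds in the test suite,
each run through the model, valuation, CEA, a 3-parameter tornado and a
10-draw PSA). Passing these tests establishes structural correctness —
conservation of mass, identity propagation, determinism — and nothing about
the clinical realism of any particular synthetic set.

## Numerical choices and problem sizes

* Row-stochasticity and occupancy conservation are enforced to 1e−9;
  probability/rate round trips and commutation identities to 1e−12.
* Degenerate comparisons: |ΔQALY| < 1e−12 renders the ICER undefined rather
  than dividing by a vanishing denominator.
* JSON configs round-trip at full double precision; YAML at 15 significant
  digits.
* Test problem sizes: 30-cycle (10-year) runs for deterministic checks,
  1,000-iteration PSA in the acceptance suite, 10,000 draws for
  distribution-mean checks, 25 random seeds for generator smoke properties.

## Known limitations

* Treatment effects are trial-period averages applied uniformly over the
  whole horizon; no waning or time-variation.
* Subsequent CV events are state- and strategy-independent, as printed.
* The post-CV layer modifies economics only; CKD-stage dynamics are
  identical in both layers.
* No age structure or secular background mortality: the per-cycle death
  risks are constant by state, so very long horizons understate late-life
  mortality.
* Healthcare-system perspective only; no societal costs, no currency
  conversion, no budget impact, no EVPI.
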