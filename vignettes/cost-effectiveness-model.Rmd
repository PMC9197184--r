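---
title: "The partitioned-survival cost-effectiveness model in psmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The partitioned-survival cost-effectiveness model in psmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

`psmcea` evaluates whether adding a PD-1 inhibitor (pembrolizumab) to a
fluorouracil/cisplatin backbone is value for money as first-line therapy
for advanced oesophageal cancer, from a healthcare-system perspective with
a willingness-to-pay (WTP) threshold of $31,304.31 per quality-adjusted
life year (three times Chinese per-capita GDP). The comparison is a
two-strategy incremental analysis: incremental cost divided by incremental
QALYs (the ICER) against the threshold.

The package is organised so that the same machinery answers the question
for any two-arm oncology comparison in which the published evidence is a
pair of Kaplan–Meier (KM) plots: overall survival (OS) and
progression-free survival (PFS) per arm, with number-at-risk tables.

## Model structure

The cohort model is a three-state partitioned-survival model: alive and
progression-free (PFS), alive with progressed disease (PD), and dead.
Occupancy is read directly off the survival curves rather than derived
from a transition matrix:

* `pfs(t) = min(PFS(t), OS*(t))`
* `dead(t) = 1 − OS*(t)`
* `pd(t) = OS*(t) − pfs(t)`

where `OS*` is the modelled overall survival after applying a
**background-mortality floor**: at each cycle the death probability is the
larger of the model-implied value `1 − OS(t+1)/OS(t)` and the probability
implied by the age-specific annual death rate in the life table, converted
to the cycle length. The floor guarantees the extrapolated cohort never
dies more slowly than the general population of the same age, which
matters in the long right tail where the fitted curves are unanchored by
data. The `min()` in the PFS row resolves any crossing of the fitted PFS
and OS curves in favour of OS; occupancies can never go negative.

This is the standard reading of such models when only marginal OS and PFS
curves are published. An explicit transition-matrix mode is deliberately
out of scope: the published evidence does not identify the PFS→death
versus PFS→PD split, so a matrix would add parameters without adding
information.

Cycles are 3 weeks (21 days); the horizon is 30 years, which is effectively
lifetime for this population (the trace is truncated earlier once less
than 1e-6 of the cohort remains alive). Costs and QALYs are discounted at
3% per year on the cycle clock, `(1.03)^(−t years)`, and all
state-occupancy accruals are half-cycle corrected by the trapezoid rule —
the value credited to a cycle is the mean of its boundary values, so
transitions effectively happen mid-cycle. Drug acquisition costs are the
exception: drugs are dispensed at the start-of-cycle visit, so they
multiply the uncorrected start-of-cycle occupancy. A year is 365.25 days
everywhere, making cycle/year conversions unambiguous.

## From published curves to model curves

**Reconstruction.** `reconstruct_ipd()` inverts a digitized KM curve plus
its number-at-risk table into pseudo individual-patient data using the
iterative KM-inversion algorithm standard in this literature: within each
risk-table interval the number of censorings is solved so that the at-risk
count implied by the curve's survival drops matches the published count at
the next boundary; censoring times are spread evenly within the interval.
Two implementation choices differ from common implementations and are
deliberate:

* it is **fully deterministic** (no random censoring placement; a single
  censoring goes to the interval midpoint), so downstream fits are exactly
  reproducible;
* digitization noise that makes survival *rise* by up to 0.005 is clamped
  to the running minimum, while larger rises are treated as real input
  errors and rejected with the offending row numbers. The 0.005 tolerance
  is roughly one pixel of a journal-resolution plot.

Beyond the last risk-table boundary no attrition information exists, so
events follow the curve's drops and everyone still at risk at the curve's
end is administratively censored there. An optional known total event
count triggers a final pass that converts tail events/censorings until the
total matches.

**Fitting.** Five parametric families — exponential, Weibull, log-normal,
log-logistic, Gompertz — are fitted to the reconstructed data by maximum
likelihood (delegated to `flexsurv::flexsurvreg()`, the field-standard
fitter) and the family with minimum AIC is selected. AIC ties (within
1e-9) break toward fewer parameters, then a fixed family order, so
selection is deterministic. With trial-sized samples (a few hundred per
arm) log-logistic and log-normal fits are often within a point or two of
AIC of each other; the pipeline simply takes the winner, and either choice
produces near-identical curves over the data range.

**The intervention arm is driven by the hazard ratio.** The base case
transforms the fitted control curve as `S_trt(t) = S_ctrl(t)^HR`
(proportional hazards), rather than fitting the intervention arm
independently. This is the only construction coherent with the one-way and
subgroup analyses, which vary the HR as *the* effect parameter; a
direct-fit mode (`fit$direct_trt_fit` in the config) exists for users who
prefer an unconstrained comparator curve.

## Parameters

| Parameter | Default (bounds) | Units / notes |
|---|---|---|
| HR OS | 0.73 (0.58–0.88) | intervention vs control |
| HR PFS | 0.65 (0.52–0.78) | |
| Pembrolizumab | 5625.75 (±50%) | $/3-week cycle, ≤ 35 cycles |
| 5-Fluorouracil | 256.67 (±20%) | $/cycle, ≤ 6 cycles, both arms |
| Cisplatin | 17.52 (±20%) | $/cycle, ≤ 6 cycles, both arms |
| Paclitaxel (2nd line) | 351.81 (±20%) | $/cycle in PD; uptake 43% / 47% |
| Routine follow-up | 55.18 (±20%) | $/cycle, applied to PFS occupancy |
| Supportive care | 125.47 (±20%) | $/cycle, applied to PD occupancy |
| AE management | 71.00–466.00 (±20%) | $/event, lump at cycle 0 |
| Utility PFS | 0.74 (0.59–0.89) | |
| Utility PD | 0.58 (0.46–0.70) | dead = 0 |
| Discount rate | 3% (0–5%) | annual, costs and effects |
| Start age | 63 (53–73) | years at model entry |
| WTP | 31,304.31 | $/QALY |

Costs are 2020 USD (the source conversion, $1 = ¥6.9, is metadata only —
no live FX). Where the design was genuinely open we chose once and exposed
the choice in the config:

* **Follow-up vs supportive care state assignment.** The sources list both
  as administration costs without a state; we bill follow-up to PFS and
  supportive care to PD, the most common convention.
* **Second-line duration.** Uptake fractions are reported but duration is
  not; paclitaxel is billed per cycle for the whole PD occupancy (weighted
  by uptake), uncapped. The line's `max_cycles` makes this testable.
* **AE incidences.** Unit AE management costs are source values but the
  per-arm incidences are not published; the shipped defaults
  (`inst/extdata/ae_profile_synthetic.csv`, also `ae_profile()`) are
  synthetic, chosen once at magnitudes realistic for this regimen class,
  and clearly labelled as such. They contribute a lump of under $200 per
  arm and have no influence on conclusions.
* **Start age and horizon.** Neither is printed in the source material;
  63 years is the typical trial median age, and 30 years is lifetime at
  that age. Both are flagged as assumptions in the run manifest; start age
  is varied 53–73 in the one-way analysis.

## Sensitivity analyses

**One-way (tornado).** Every parameter in the table above is set to its
low and high bound with the rest at base; two full model runs per
parameter, rows sorted by ICER spread. Because the ICER is exactly affine
in the pembrolizumab cycle price (the price enters incremental cost
linearly and touches nothing else), the base ICER must equal the midpoint
of the two price-extreme ICERs — a property the test suite checks to 1e-6
relative, and a useful canary for accounting bugs.

**Threshold analysis** exploits the same affinity: the break-even price at
which ICER = WTP is solved from two model evaluations in closed form, then
verified by a confirmation run (relative ICER error ≤ 1e-4).

**Probabilistic (PSA).** 1000 Monte-Carlo draws: utilities from beta and
costs from gamma distributions parameterised by method of moments with
`sd = (high − low)/3.92` (ranges treated as 95% intervals); hazard ratios
from lognormal distributions with `sdlog = (ln high − ln low)/3.92`.
Lognormal HRs are our choice — the sources name only beta and gamma — as
standard practice for ratio parameters; the config can freeze HRs instead.
If a utility's variance is infeasible for the beta support it is scaled
down with a warning. The discount rate and start age stay fixed in the
PSA. Each draw is a full model run; the cost-effectiveness acceptability
curve reports, per WTP value on a $0–$340,000 grid ($2,500 steps), the
fraction of draws with non-negative net monetary benefit
`WTP·ΔQALY − Δcost` — a quantity necessarily nondecreasing in WTP for two
strategies.

**Subgroups** rerun the pipeline with subgroup hazard-ratio pairs
(squamous histology 0.72/0.65; PD-L1 CPS ≥ 10 0.62/0.51).

## The synthetic-trial generator

`synth_trial()` emulates the *product* of curve digitization, not the
digitization itself. Control-arm OS and PFS event times are log-logistic
with the published control medians (9.8 and 5.8 months) — the log-logistic
scale parameter *is* the median, which makes calibration exact — and
shapes 1.5 / 1.6, free parameters chosen once for plausible
oncology-trial tails. Intervention-arm times are drawn from
`S_ctrl(t)^HR` by inverse-CDF sampling (HR 0.73 / 0.65), so the generated
arms satisfy proportional hazards by construction. Censoring is an
exponential dropout hazard of 0.01/month plus administrative cutoff at
22.6 months (the trial's median follow-up); sample size is 374 per arm
(749 randomized, rounded down). The KM estimate of each arm is sampled on
a 0.25-month grid with a 3-month risk table — the shapes a careful
digitization would produce.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: digitization pixel noise beyond the grid
discretisation; within-patient coupling of OS and PFS (endpoints are
simulated independently, which is all the partitioned-survival model
consumes, but real joint data would constrain PD occupancy more);
non-proportional hazards (delayed separation of immunotherapy curves);
informative censoring. Conclusions about the real trial should rest on
reconstruction from the actual published curves, which the pipeline
accepts as CSV inputs.

## Numerical choices and problem sizes

* Trace conservation is exact by construction; tests assert row sums to 1
  within 1e-9 and monotone death.
* Degenerate inputs: all-censored IPD, empty curves, rising risk counts,
  ages beyond the life table, and non-positive parameters raise classed
  errors (`psmcea_invalid_input` / `psmcea_invalid_parameter`).
* Ties at equal event/censoring times follow the events-first
  product-limit convention via `survival::survfit()`.
* Reconstruction round-trip accuracy on the default fixtures is asserted
  at ≤ 0.02 sup-norm between the input digitized curve and the KM curve of
  the reconstructed IPD, on all four arm × endpoint fixtures.
* Parameter-recovery checks simulate n = 5,000 per family with ~20%
  censoring and require every parameter within 10% of truth (5% for the
  uncensored log-logistic case); at that size the log-logistic also wins
  AIC on log-logistic data, which is not guaranteed at trial size.
* The shipped analyses use 1000 PSA draws and a 374/arm synthetic trial;
  both complete in well under a minute on a single core.

All randomness flows through explicit integer seeds; `run_pipeline()`
derives per-stage seeds from its master seed, and repeated runs are
byte-identical.

## Limitations

The model inherits the limitations of its evidence base: no grade 1–2
adverse-event costs; a single second-line therapy; utilities borrowed from
published studies rather than trial EQ-5D; proportional hazards assumed
wherever an HR drives a curve. The partitioned-survival structure cannot
represent treatment effects that differ between the PFS→PD and PFS→death
pathways. None of these can be fixed from the published evidence alone;
all are surfaced as config switches or manifest flags rather than silent
assumptions.
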