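---
title: "Methods: bottom-up costing, uncertainty analysis and package rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up costing, uncertainty analysis and package rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnccost)
```

## The costing model

`hnccost` estimates what it costs a public tertiary-care hospital to
deliver head and neck cancer treatment, service by service, from the
bottom up. The unit of analysis is a *service*: outpatient consultation
(radiotherapy and otolaryngology clinics), inpatient care, surgery, and a
radiotherapy course delivered by one of five technique–machine classes
(2-DRT on cobalt-60, 2-DRT on linear accelerators, 3D-CRT, IMRT on plain
linacs, IMRT on an image-guided machine). Every resource consumed during
one accounting year is valued and attributed to services:

* **Capital** (equipment, furniture) is converted to an equivalent annual
  cost: `EAC = price / A(L, r)` with annuity factor
  `A(L, r) = (1 − (1 + r)^−L) / r`, lifespan `L` in years and discount
  rate `r` (fraction/year). This values capital as the constant annual
  payment with the same present value as the purchase, the standard
  treatment in facility costing; at `r = 0` it degenerates to
  straight-line `price / L`, and EAC is increasing in `r` and decreasing
  in `L`. There is no salvage value: items are assumed used to the end of
  their life.
* **Space** is costed as rent — floor area (sqft) times a rental price
  (INR/sqft/year) — rather than annualized construction cost, because a
  market rental price is observable where historical construction cost is
  not.
* **Salaries** are split over activities by *proportional time
  contribution*: each staff member's gross salary times their time
  fraction per service. Fractions may sum to less than one; the remainder
  is reported as unallocated rather than silently redistributed.
* **Shared resources** (overhead bills, jointly used items) are split by
  an apportionment rule: a normalized weight vector derived from an
  allocation statistic (floor area for water, patient-time proportions
  for electricity, patient proportions for laundry, diet counts for
  dietetics). Shares are `total × weight`, so apportionment conserves
  cost exactly — a property the test suite checks on 1000 randomized
  fixtures.
* **Indirect cost centres** (laboratory, pharmacy, radiodiagnosis) are
  not re-costed from their own inventories; they enter as priced
  per-patient inputs (e.g. a diagnostics panel price), mirroring how such
  estimates are typically carried over from prior studies of the same
  facility.

The **unit cost** of a service is its annual pool divided by its annual
volume, in the service's natural unit: per visit, per bed-day, per
treated patient. Input-wise **cost shares** aggregate the same
allocations by resource group (salaries; equipment/furniture; space;
overheads and consumables).

Key parameters, with defaults:

| parameter | unit | default | why |
|---|---|---|---|
| `discount_rate` | fraction/year | 0.05 | conventional public-sector rate for annualization |
| `space_rent_per_sqft` | INR/sqft/year | 1200 | plausible commercial rent for the emulated city tier |
| `market_to_hospital_ratio` | – | 0.85 | deflates market prices of non-medical items to procurement level |
| `inr_per_usd` | INR/USD | 61.02 | the costing year's World Bank exchange rate |

Money is carried at full double precision throughout and rounded only at
presentation (2-decimal INR in CSV outputs, half-up integer USD).

## Out-of-pocket expenditure

Patient spending is classified as direct **health** (diagnostics,
radiotherapy charges, drugs including chemotherapy, hospitalization, user
fees) and direct **non-health** (transport, boarding, food); indirect
(productivity) costs are out of scope. Records are per-patient course
totals; the prospective cohort's daily interviews are assumed already
summed to course level, so the cohort label is inert in estimation and
both cohorts pool into one sample — `summarize_oop()` treats it as
metadata only. Per combination the package reports the arithmetic mean
with a 95% t-interval (`mean ± t(n−1, 0.975)·SE`), both including and
excluding non-health items. The t-interval is a deliberate, conventional
default: with right-skewed gamma-like spending and cohorts of ~50 it
achieves close to nominal coverage (the suite checks 95% ± 3 points over
500 simulated cohorts). Pre-hospital spending (care sought at other
providers before presentation) is summarized on its own line and never
added into course totals.

The precision-based sample size is `n = ⌈(z·σ/d)²⌉` with a floor of 1.
For σ = 412, d = 40 and 95% confidence this returns **408**; the
function returns the formula value and makes no attempt to reproduce
any particular rounded-up figure.

## Probabilistic sensitivity analysis

Prices — not quantities — are the uncertain inputs: resource-use patterns
in comparable tertiary centres are similar, while salaries and
procurement prices vary widely across states. Each resource category gets
a variation rule: a distribution family and a range below/above base.
Defaults: salaries −75%/+20% (gamma), equipment ±40% (normal), drugs and
consumables ±100% (gamma), furniture/stationery ±25% (normal),
building/space and laboratory tests ±50% (normal), other overheads ±25%
(normal). Stated ranges are mapped to distributions by interpreting
the range as the central 95% interval: `SD = (lower + upper)·base/(2z)`
with `z = 1.96`. Normal draws use that SD directly (truncated at zero);
gamma draws are moment-matched to the same mean and SD, so the range
asymmetry is absorbed into the gamma's natural right skew. The
gamma/normal assignment is configurable; the defaults put gamma on the
inherently positive, wide- or asymmetric-range categories.

Each of `n_draws` (default 1000) Monte Carlo iterations redraws every
resource price independently and re-evaluates all unit costs; results are
summarized as the draw mean with empirical 2.5/97.5 percentile bounds.
Implementation note: annualization and apportionment are linear in price,
so each draw rescales the item-level allocation table by the ratio of
drawn to base price — algebraically identical to rebuilding the costing
from scratch per draw, and fast enough that the default pipeline (1000
draws, ~70 items, 10 services) runs in well under a second. Draws
producing a negative service total (possible only under extreme normal
rules) are excluded and counted. No correlation between resources is
modelled: variation is univariate per category by design.

## Package rates

A package rate is the bundled payment for one treatment episode:
`Σ (unit cost × quantity)` over its components, plus the per-patient
diagnostics cost, plus the mean direct-health OOP spend of the matching
treatment combination — the patient's share belongs in the rate because
public-hospital patients pay substantial amounts out of pocket for drugs
and diagnostics even when care is subsidized. Interval bounds are sums of
component bounds (conservative interval arithmetic; a PSA-based
re-simulation of whole packages would be narrower but is deliberately not
the default). Episode quantities — consultations per course, bed-days
when surgery is involved — are not observable from published unit costs,
so they are configuration with documented defaults (3 radiotherapy-clinic
visits; 7 bed-days for surgical packages) rather than estimates. Composed
rates are therefore internally consistent with this package's unit costs
but are not transcriptions of any external rate table; the shipped
insurance-scheme rates (CGHS, ESIS, RSBY-plus, RAS, RGJAY) are static
reference data used only for comparison.

## The synthetic facility generator

The generator is the package's study-conditions module: it emulates one
accounting year of the reference department so that every downstream
stage is testable against known ground truth.

**Calibration.** Target annual cost pools per service are the target unit
costs times the printed service volumes (1227 consultations, 3334
bed-days across 225 admissions, 583/222/77/17/40 radiotherapy courses by
technique). The inpatient pool is defined as the residual that closes the
department total of INR 40,993,017 — the published service-level
percentages are not exactly consistent with unit costs × volumes, and the
residual convention preserves the quantities the pipeline reports (unit
costs and the total). The 57 IMRT courses are split 40 on the
image-guided machine and 17 on plain linacs; this split is not a recorded
figure and was chosen once for plausibility against the department's
service-share pattern. Per-service input mixes start from the known
pattern (cobalt salary-led at ~40% with 27% equipment; equipment rising
to 57% for linac 2-DRT and 69% for image-guided IMRT) and are raked by
iterative proportional fitting so the pool-weighted global shares equal
42.6/29/20.7/7.7 exactly. The generator then constructs concrete records
— a staff roster of shared senior cadres (oncologists, physicists,
carrying 30% of the salary budget across all department services in
proportion to service pools) and dedicated residents/technicians/nurses;
capital items whose prices are back-calculated through the annuity factor
so annualization recovers the intended annual charge; rooms, consumables
and overhead bills, three of which are shared and exercise the
apportionment rules.

**Noise.** One dimensionless `noise_scale` multiplies all dispersion:
lognormal price jitter with sd `0.05 × noise_scale` on every salary and
price, and the patient-spending coefficient of variation. At
`noise_scale = 0` the dataset is fully deterministic and costing it
returns the calibration targets exactly (the suite checks shares within
1 percentage point and unit costs to numerical precision); at the default
`1`, prices carry ~5% jitter — a realistic level of ledger heterogeneity
— and recovered quantities sit within a few percent of target.

**Patients.** Each of `n_patients` (default 474: 159 prospective, 315
retrospective) draws a base combination from the treatment mix
(55.4/29.3/10/5.3%), a technique class from the modality distribution,
and gamma-distributed course totals (mean per combination, cv 0.65 —
chosen to match the dispersion implied by reported interval widths at
plausible subgroup sizes; gamma because spending is non-negative and
right-skewed). Itemized amounts are fixed shares of the drawn total, so
items sum to totals exactly. Rare combinations (e.g. surgery + IMRT +
chemotherapy, expected ~1.5 of 474) can be absent from a finite cohort;
the pipeline then skips that package and logs it rather than imputing.

**What the generator does not emulate:** clinical outcomes, disease
progression, length-of-stay distributions, within-year seasonality,
correlated price shocks, item-level spending correlation structure, and
any real patient's data. Passing tests demonstrate that the *methods*
recover known inputs under realistic structure — not that the synthetic
numbers are field data.

## Numerical choices and degenerate inputs

* Apportionment weights must be non-negative and sum to 1 within 1e-9;
  all-zero weight vectors and fraction sums above 1 + 1e-9 are errors,
  not warnings.
* Zero service volume with a nonzero pool is a domain error (no silent
  infinities); zero volume with zero cost yields `NA`.
* `annuity_factor` handles the `r = 0` limit explicitly; the r→0
  behaviour is verified against straight-line at `r = 1e-9`.
* USD conversion rounds half away from zero (`round_half_up`), not
  banker's rounding — this reproduces every printed INR→USD pair the
  suite checks.
* Seeding: every public entry point runs under a private RNG state
  restored on exit; one global seed fans out to per-stage streams via a
  Lehmer-style splitting rule, keeping derived seeds below 2³¹. Two runs
  with the same seed are byte-identical, file by file.

## Problem sizes used by the test suite

Deterministic checks run on hand-built fixtures of one to three
resources. Stochastic checks use: 10⁴ patients for mean/frequency
convergence (2–3 SE bands), 10⁵ draws for sampler quantile recovery,
500 cohorts of 50 for CI coverage, 1000 randomized apportionment
fixtures, and full pipelines at 40–1000 PSA draws. The complete suite
runs in a few seconds on one CPU.

## Known limitations

Single-facility scope (no between-hospital variation beyond price PSA);
one accounting year with no inflation adjustment; surgery costed for a
single surgical unit; no correlation between varied prices; package
episode quantities are assumptions, not estimates; and the scheme
comparison treats reference rates as fixed constants.
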