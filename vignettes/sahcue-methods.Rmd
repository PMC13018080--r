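---
title: "Cost-utility modelling of cerebral-infarction reduction in aSAH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility modelling of cerebral-infarction reduction in aSAH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahcue)
```

This vignette is the package's account of its science: the decision model,
the economic rules, the calibration behind the mechanistic engine, the
choices made where the design was genuinely open, and the limits of what the
shipped tests demonstrate.

## The decision problem

Candidate therapies for aneurysmal subarachnoid hemorrhage (aSAH)
increasingly target the occurrence of new cerebral infarction during the
initial hospitalization, the measurable event on the causal path from
delayed cerebral ischemia to death and disability. The framework asks: for
an intervention costing $c$ per patient that lowers the infarction
proportion by $\Delta p$ percentage points, what is the incremental cost per
quality-adjusted life year (QALY) gained, and does it clear conventional
willingness-to-pay (WTP) thresholds? Because the question is posed *before*
a Phase 3 trial, every input is an explicit, replaceable assumption.

## Cohort model

A cohort of $n = 100$ patients is split into an infarction stratum
(base case $p = 0.35$) and a no-infarction stratum. Each stratum occupies
three functional states — independent (mRS 0–2), dependent (mRS 3–5), dead —
evaluated at $\{0.25, 1, 2, 3, 5\}$ years and annually thereafter to 30.
Dynamics are a simple Markov chain: per-interval transition matrices up to
year 5 (dead absorbing), then a single annual mortality probability applied
equally to both alive states. Equal post-5-year mortality is what encodes
the *plateau* assumption — the independent:dependent mix of survivors is
constant after year 5, so late QALY loss is driven purely by death.
`simulate_cohort()` evolves distributions only through
`evolve_states()` (left multiplication by row-stochastic matrices), so any
trajectory equals explicit matrix-power evolution by construction; the test
suite verifies this against an independent brute-force implementation on 50
random schedules at $10^{-10}$.

Nursing-home (NH) occupancy runs on the same grid. The 3-month occupancy
seeds the series; 70% of residents remain at 1 year, and 61% / 36% of the
1-year residents remain at 2 / 5 years. The 3-year retention is not
published: we interpolate geometrically between the 2- and 5-year anchors
($r_3 = 0.61 \cdot (0.36/0.61)^{1/3}$), a smooth monotone choice consistent
with both. Occupancy is always capped at the alive fraction.

**Occupancy after year 5.** The source narrative is contradictory: one
sentence promises no further NH discharges after year 5, another states an
"annual rate of continuing in nursing home admission" of 13%. Three rules
are implemented (`nursing_home$post5y_mode`):

* `share_of_alive` (default): 13% of survivors reside in a NH each year;
* `retain_all`: the 5-year occupancy is carried forward with deaths removed
  in proportion to cohort mortality;
* `retain_13pct`: occupancy decays by the factor 0.13 per year.

The default differs from the most literal "no discharges" reading for an
arithmetic reason: under `retain_all` the retention product leaves only
about 4% of the cohort in a NH after year 5, and the published 30-year
cost increments — especially the no-infarction stratum's — are then
unreachable by a wide margin. The 13%-of-survivors reading reproduces the
magnitude of those increments and is therefore used for calibration; the
other two rules remain available for sensitivity analysis.

## Economics

Cohort cost to horizon $h$ sums three components (all 2025 USD):

1. **Acute hospitalization**, charged once to every admitted patient:
   $122,200.96 with, $89,997.00 without infarction.
2. **Disability care**: annual rates $14,293.80 (mRS 0–2) and $15,633.30
   (mRS 3–5) applied to alive patient-years. The first post-hospital year
   uses the 1-year state mix; years 2–5 are costed at the three evaluated
   years (2, 3, 5) and the sum is expanded by ×1.33 to a 4-year block
   (3 × 1.33 ≈ 4, with the evaluation years chosen where the mix is still
   moving); after year 5 the rates apply unchanged to survivors.
3. **Nursing home**: $114,665/year on the occupancy series, additive on top
   of disability care; the first-year exposure is the 3-month-seeded
   occupancy ×0.85 (discharges between 3 and 12 months), and the same
   ×1.33 block expansion applies to years 2–5.

Benefits are **point-in-time QALYs**:
$n\,(f_{\text{ind}} \cdot 0.74 + f_{\text{dep}} \cdot 0.38)$ at the horizon
itself — a deliberate cross-sectional convention, not an integral over time,
so the 30-year QALY total (18.3) is *smaller* than the 1-year one (56.9).

No discounting is applied: the source arithmetic is consistent with none and
states no rate. A `discount_rate` hook exists (default 0) for users who want
discounted variants; it scales each evaluated year's cost by
$(1+r)^{-t}$.

Money is held as numeric dollars throughout (all magnitudes are far below
the scale at which doubles lose cent precision) and displayed with
commercial half-up rounding to the dollar, matching the printed tables; QALY
displays use one decimal.

## Anchor mode and mechanistic mode

The published analysis reports stratum-level aggregates (the *anchors*): at
1 and 5 years, cumulative cost and point QALYs for the 35-patient infarction
and 65-patient no-infarction strata; at 30 years, the years-5-to-30 cost
*increments* plus 30-year QALYs. The increment reading is forced by
arithmetic: the 5-year cohort total plus both increments equals the printed
30-year total to $0.20, while a cumulative reading fails by more than $21M.
`calibrate_anchors()` verifies this identity (tolerance $5) and divides by
stratum size; the printed per-patient figure for the no-infarction stratum
at 1 year ($119,922.40) disagrees with the division by $0.31 and is treated
as a display rounding, the stratum total being authoritative.

**Anchor mode** (default) serves results directly from these anchors:
1-year totals are affine mixtures
$n\,[p\,c_{\text{ci}} + (1-p)\,c_{\text{no\_ci}}]$ for any $p$, which
reproduces the published 1-year scenario column within $1. The published 5-
and 30-year scenario cells for the reduced proportions are *not* affine in
$p$ (their generative detail is not recoverable), so they are stored
verbatim and served for the standard proportions only. ICERs in anchor mode
divide by QALY gains rounded to one decimal — the precision at which the
aggregate estimates are published.

**Mechanistic mode** regenerates everything from the schedule and the cost
rules above, for any proportion and horizon.

## Calibrating the schedule

The three-state schedule itself (3-month mixes, year 1–5 transitions,
post-5-year mortality, 3-month NH occupancy) is cited to sources whose
numbers are not reproduced in the text. The shipped defaults are therefore
**calibration products**, solved by `calibrate_schedule()` so that the
mechanistic engine reproduces the anchors, and flagged
`calibrated: true` in the configuration. Structure of the solve, per
stratum:

* post-5-year mortality $q$ solves $u_{30} = u_5 (1-q)^{25}$ in closed form
  (per-patient point utilities $u_h$ are anchor ratios);
* the 1- and 5-year mixes lie on utility iso-lines
  $0.74\,i + 0.38\,d = u_h$; their positions are free parameters;
* 3-month NH occupancy is back-solved from the 1-year cost anchor;
* dead fractions at years 2 and 3 interpolate between the 1- and 5-year
  values with a free shape exponent, the survivor mix linearly;
* the free parameters minimize the squared residuals of the years-2–5 cost
  block and the 5-to-30-year increment under monotonicity constraints, with
  a small interior regularizer to select a central solution when exact fits
  form a manifold.

The solve is deterministic (fixed multi-starts, Nelder–Mead) and takes a
few seconds. Residuals, reported by `mechanistic_residuals()` and asserted
in the test suite, are part of the package's stated accuracy:

* infarction stratum: all three horizons reproduced to within $15;
* no-infarction stratum: 1-year exact; the 5-year anchor is **structurally
  infeasible** — it lies below the minimum cost the model's own rates can
  generate. Its 5-year QALY anchor (42.6/65 = 0.655) forces ≥ 88% survival
  with a heavily independent mix, whose disability and NH costs already
  exceed the published 5-year increment; the best fit overshoots by about
  $0.8M (≈ 6.5% of the stratum total) at 5 years and carries ≈ $0.4M
  (≈ 0.9%) to 30 years.

Two calibration artifacts deserve emphasis. The anchors pin down *utility
mixes*, not clinically attested distributions: the exact-fit solution puts
the infarction stratum at 1 year at roughly 8% independent / 90% dependent /
2% dead, and the no-infarction stratum at ~0% 1-year mortality (its QALY
anchor alone caps mortality at 10.8%). Forcing clinically typical mixes
instead costs on the order of $150k in 5-year residual. The schedule should
therefore be read as "whatever reproduces the published aggregates", never
as outcome estimates.

## Cost-utility analytics

$\mathrm{ICER} = (n c - S)/\Delta Q$ with cost saved $S$ and QALY gain
$\Delta Q$ between the base case and the reduced-proportion scenario. A zero
gain makes the ICER undefined (an error, never ±∞ in tables). WTP
classification uses *strict* "<" (the thresholds are published as
"<$50,000" etc.); a negative ICER with positive gain is *dominant*, and the
raw negative value is retained in tables. One published qualitative claim is
inconsistent with its own table: the $5,000 intervention at 5 years with a
5-point reduction is described as cost-effective under <$50,000, but the
printed cell is $53,840/QALY, which a strict rule classifies under <$100,000
instead. The package follows the table arithmetic; the corresponding
acceptance expectation is intentionally left failing to document the
discrepancy rather than silently picking a side.

## Sensitivity analysis

`one_way()` scales one input while holding the rest fixed and reports the
ICER change from the anchor scenario. The anchor is not stated in the
source; it is inferred as (5-year horizon, 15-point reduction,
$5,000/patient), the only combination that reproduces the published sweep
deltas exactly: a ±10% QALY sweep gives $A(1/m - 1)$ = +$20,991/−$25,656
around the anchor ICER $A$, and a ±20% intervention-cost sweep gives
$\pm 0.2\,n c/\Delta Q = \pm\$30,303$. The anchor is configurable.

The QALY-gain and intervention-cost sweeps act directly on the ICER
arithmetic and run in anchor mode. Nursing-home and independent-band annual
costs require recomposing scenario costs and run mechanistically. With ±20%
ranges the NH sweep is the widest bar, matching the published narrative of
NH costs as the dominant uncertainty driver; its magnitude (≈ ±$35k) is
smaller than the published "approximately ±$100,000", whose recomposition
details (and the range behind the independent-band sweep, published only as
±$14,496) are not recoverable from the text — these two bars are therefore
reported, not asserted against golden values. Ordering ties in
`tornado_table()` break alphabetically.

## Configuration, fixtures, and what the tests show

All constants live in one YAML document (shipped at
`default_config_path()`, every key annotated with its provenance class);
any subset may be overridden, unknown keys error, and every structural
invariant — utility ordering, non-negative money, retention bounds,
distribution normalization, strictly increasing thresholds, the 30-year
identity — is validated on load. `generate_fixtures()` emits the default
configuration plus seeded perturbations (unit costs × U(0.8, 1.2), utilities
jittered within their ordering bounds). The perturbed fixtures emulate
*parameter* uncertainty only: they keep the cohort structure, the plateau,
and the published anchors fixed, so property tests passing on them says
nothing about structural misspecification, correlated parameter errors, or
real-world outcome heterogeneity (age, severity confounding between
infarction and outcome — which the source itself flags as a possible
overestimate of benefit).

Problem sizes throughout the suite are desk-scale by design: 100-patient
cohorts, 30-year grids (36 time points), 36-cell ICER grids, 50-schedule
oracle sweeps; the full suite runs in a few seconds.

## Known limitations

* Indirect costs, informal caregiving, and monitoring/surveillance costs
  are excluded, as in the source analysis.
* The 5- and 30-year scenario cells for reduced proportions are served from
  stored published values; mechanistic recomputation of those cells
  deviates from them (the published cells are not affine in the proportion,
  and their generative detail is unpublished).
* No probabilistic sensitivity analysis: uncertainty handling is one-way
  deterministic sweeps only.
* The calibrated schedule is an aggregate-matching construct, not an
  epidemiological estimate (see the artifacts above), and the no-infarction
  stratum carries an irreducible documented residual.
* CPI-based inflation of heterogeneous source years is folded into the
  already-adjusted default costs; `inflation_adjust()` exposes the
  operation but ships no index series.
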