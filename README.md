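# sahcue

Pre-trial cost-utility modelling of therapeutic interventions that reduce
cerebral infarction in aneurysmal subarachnoid hemorrhage (aSAH).

## The problem

Phase 3 trials in aSAH are expensive, and most candidate agents target
delayed cerebral ischemia through a reduction in new cerebral infarction
during the initial hospitalization. Before committing to such a trial it is
useful to know whether an intervention of a given price could ever be
cost-effective, given a plausible effect size. `sahcue` implements a
decision-analytic framework for exactly that question, aimed at trialists,
health economists and pharmacy decision-makers.

## The model

A hypothetical cohort of 100 aSAH patients is split by infarction status
(base case: 35% develop cerebral infarction). Each stratum moves through
three functional states — independent (mRS 0–2), dependent (mRS 3–5), dead —
on the grid {3 months, 1, 2, 3, 5 years, then annually to 30}, via a simple
Markov model; after year 5 the survivor mix is frozen (outcome plateau) and
only mortality acts. Nursing-home occupancy is seeded at 3 months and decays
along the published retention schedule (70% to 1 year; 61% and 36% of the
1-year residents at 2 and 5 years).

Cohort cost over a horizon *h* is

```
cost(h) = acute + disability care + nursing home
```

with the acute stay charged to every admitted patient ($122,200.96 with /
$89,997.00 without infarction), annual disability-care rates by band
($14,293.80 mRS 0–2, $15,633.30 mRS 3–5), nursing-home residence at
$114,665/year (×0.85 in the first year; the years 2–5 block is the sum of the
2-, 3- and 5-year evaluations ×1.33), all in 2025 USD. Benefits are
**point-in-time QALYs**: `n · (f_ind · 0.74 + f_dep · 0.38)` at the horizon,
not a time integral.

For an intervention costing `c` per patient that reduces the infarction
proportion, the incremental cost-utility ratio is

```
ICER = (n·c − cost saved) / QALYs gained
```

classified against willingness-to-pay thresholds <$50k, <$100k, <$150k per
QALY (negative ICER with positive QALY gain = dominant). One-way
deterministic sweeps of the key inputs are summarized tornado-style.

Two engines are available: **anchor mode** (default) reproduces the
published aggregate estimates from per-stratum anchors; **mechanistic mode**
regenerates everything from the three-state schedule and cost primitives
(the schedule is calibrated, not literature — see the methods vignette).

## Worked example

```r
library(sahcue)
cfg <- load_config(default_config_path())

scenario_table(cfg, horizons = 1)
#>    mode horizon p_infarction total_cost total_qaly
#>  anchor       1         0.35   13777940       56.9
#>  anchor       1         0.30   13522844       58.2
#>  anchor       1         0.25   13267749       59.5
#>  anchor       1         0.20   13012653       60.8
```

At 1 year the base-case cohort costs $13,777,940 and holds 56.9 QALYs;
preventing infarction in 15 of the 100 patients saves $765,287 and gains
3.9 QALYs.

```r
subset(icer_grid(cfg, horizons = 5), cost_per_patient == 5000)
#>  horizon reduction_pct cost_saved qaly_gain  icer     wtp_class
#>        5             5     462312       0.7  53840 ce_under_100k
#>        5            10     856707       1.8 -198171      dominant
#>        5            15    1261986       3.3 -230905      dominant
```

A $5,000/patient intervention is dominant (saves money **and** gains QALYs)
at 5 years for 10- and 15-point reductions; at a 5-point reduction it costs
$53,840 per QALY gained.

```r
tornado_analysis(cfg)[, c("parameter", "delta_low", "delta_high")]
#>            parameter delta_low delta_high
#>              nh_cost     35402     -35402
#>  longterm_cost_mrs02    -32491      32491
#>    intervention_cost    -30303      30303
#>            qaly_gain    -25656      20991
```

Nursing-home cost is the dominant driver of ICER uncertainty; a ±10% change
in the QALY gain moves the anchor ICER by −$25,656/+$20,991.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sahcue.R",package="sahcue"))')" \
    scenarios --out out/
```

with subcommands `scenarios`, `icer-grid`, `tornado`, `drugcost`,
`fixtures`.

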