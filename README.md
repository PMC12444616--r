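# pcbbioleach

Process modelling of copper bioleaching from printed circuit boards
(PCBs), for bioprocess engineers and environmental-biotech researchers
evaluating column-based e-waste leaching designs.

PCB powder is ~20–25% w/w metallic copper. Ferric iron dissolves it,

    Cu0 + 2 Fe3+ -> Cu2+ + 2 Fe2+

and iron-oxidizing bacteria (*Acidithiobacillus ferrooxidans*) regenerate
the Fe3+. The package models the loop design in which leaching happens in
a packed-bed column of PCB powder while the culture stays in a stirred
tank that feeds the column and re-oxidizes its effluent.

## What it computes

* **Column leaching** (`simulate_column`): well-mixed (CSTR) balances in
  mol/L with rate law `k (Cu0 - Cu2+) Fe3+`, explicit solid-inventory
  depletion, stoichiometric coupling `m = 2`, fixed-step Euler at
  Δt = 0.1 min, refeed (recirculation) mode, extraction metrics.
* **Coupled loop** (`run_coupled`): discrete stirred-tank balance with
  `V_rim = V − Q Δt` dilution, Monod growth on Fe2+ with quadratic Fe3+
  and Cu2+ toxicity, and a trigger-driven scheduler (flow changes, medium
  replacements, metabolic-rate / concentration / crossing triggers). Two
  reference operating strategies ship as `schedule_sim1()` and
  `schedule_sim2()`.
* **Calibration** (`fit_rate_constant`): deterministic least squares for
  the rate constant over all three measured species, plus fixed-parameter
  R² scoring.
* **Energy & carbon footprint** (`stirred_energy`, `pump_energy`,
  `monte_carlo`): stirred-tank vs pump energy under explicit bases, and a
  Monte Carlo propagation of a per-litre life-cycle inventory with 10%
  characterization-factor uncertainty. The shipped factor table is an
  explicitly labelled synthetic placeholder, so only structural results
  (shares, signs, monotonicity) are meaningful.
* **Synthetic data** (`generate_outflow_series`): seeded noisy outflow
  series with a bench-like sampling cadence, so the whole pipeline runs
  with no external data.

## Worked example

```r
library(pcbbioleach)

geom <- column_geometry()        # 20 cm x 2.8 cm, eps 0.55, 200 g powder
pore_volume(geom)                # 0.0677 L
superficial_velocity(25, geom)   # 4.06 cm/min
superficial_velocity(5, geom)    # 0.81 cm/min

feed <- inflow_program("constant", fe3 = 10 / AW_FE)   # ~10 g/L ferric
low  <- simulate_column(geom, chem_kinetics(), feed, 5, 38 * 60)
extraction_metrics(low, geom)
#> $extracted_g          43.4
#> $efficiency_fraction  0.857
#> $rate_g_per_h         1.14

run1 <- run_coupled(schedule_sim1())
run2 <- run_coupled(schedule_sim2())
time_to_efficiency(run1, 0.95) / 24   # 7.25 days
time_to_efficiency(run2, 0.95) / 24   # 6.26 days
```

The 38 h low-flow run extracts 43.4 g of the 50.6 g copper inventory
(85.7% efficiency) at 1.14 g/h with a ~3.8 g/L Cu outflow plateau — the
behaviour the shipped rate constant was calibrated to. The refined
operating schedule (`sim2`) reaches 95% leaching efficiency about a day
earlier than the baseline (`sim1`) because earlier, slower recirculation
keeps the bacterial metabolic rate matched to the column's ferrous output
and the milder medium replacement preserves the culture.

The `analysis/` directory holds the narrative drivers
(`01_column_leaching.R` … `04_lca_monte_carlo.R`); each prints its
findings and writes tables under `results/`.

## Notes on provenance

Kinetic and biological parameters (`k`, `mu_max`, `K_S`, `Y_NS`, `mu_d`,
`mu_tox`) are calibrated stand-ins, documented as such, not published
constants. The characterization-factor table is synthetic; supply your own
via `read_cf_table()` for any absolute footprint claim. See the methods
vignette (`vignettes/bioleaching-process-model.Rmd`) for the full model
description, design decisions, and limitations.
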