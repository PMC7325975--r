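# rampulse

Design, simulation and inference for **gradual-versus-abrupt stressor
delivery** experiments — the question of whether the *rate* at which a
stressor arrives matters when the total exposure is held fixed.  The
package is modelled on liquid-culture heavy-metal assays with filamentous
soil fungi: a panel of isolates is grown under a control arm, a *gradual*
arm in which the copper concentration is ramped up by daily additions, and
an *abrupt* arm in which it jumps directly to the final concentration,
with both treated arms equalised in final concentration **and** in
dose-days (the area under the concentration–time curve).

For whom: stress ecologists and ecotoxicologists who want to design
dose-day-equalised exposure schedules, power-check an isolate-panel
analysis before running it, or analyse the resulting replicate tables.

## What it computes

* **Schedules** — `build_gradual_schedule()`, `build_abrupt_schedule()`,
  `dose_days()`, `check_equivalence()`.  With a final concentration *c*
  over *n* days, the ramp delivers *c(n+1)/2* dose-days and a step on day
  *s* delivers *c(n−s+1)*; the default pair (*n* = 9, *s* = 5) is exactly
  equivalent at 5*c* mM·day.
* **Synthetic experiments** — `generate_isolate_panel()` and
  `simulate_experiment()` produce replicate tables (default 17 isolates ×
  3 treatments × 5 replicates = 255 units) from a mechanistic
  logistic-growth / saturable-biosorption model whose presets realise the
  four qualitative reaction patterns.
* **Effect sizes** — per isolate, the unstandardised effect
  ES = mean(treated) − mean(control) with a 9999-resample percentile
  bootstrap CI (`bootstrap_ci()`), and the gradual-vs-abrupt contrast
  Δ = ES_abrupt − ES_gradual with a studentized bootstrap p-value
  (`compare_es()`).
* **Classification** — `classify_pattern()` labels each isolate
  `no_effect`, `uniform_reduction`, `gradual_worse` or `abrupt_worse`
  from the bootstrap evidence; `classify_strategy()` places it in the
  growth × accumulation strategy quadrants split at panel medians.
* **Classical tests** — `anova_tukey()` (pooled-MSE studentized-range
  HSD) and `pearson_ci()` (Fisher-z interval).
* **Phylogenetic signal** — `blomberg_k()` and `perm_test_k()`
  (tip-permutation null) over the six isolate-mean responses.
* **Orchestration** — `run_pipeline()` runs every stage and writes tidy
  CSVs plus a run log; `inst/scripts/rampulse-cli.R` is a thin
  command-line front end (`simulate`, `analyze`, `physignal`, `schedule`,
  `all`).

## Worked example

```r
library(rampulse)

panel  <- generate_isolate_panel(4, seed = 1)   # one isolate per preset
design <- experiment_design(isolate_ids = names(panel))
tab    <- simulate_experiment(design, panel, seed = 1)

effect_size_table(tab, "biomass_g", n_boot = 9999, seed = 2)
#>   isolate es_gradual es_abrupt     delta p_boot
#> 1   ISO01    -0.0132   -0.0259 -1.28e-02 0.6124
#> 2   ISO02    -0.9352   -0.9352 -1.63e-05 0.9704
#> 3   ISO03    -1.9071   -1.7969  1.10e-01 0.0004
#> 4   ISO04    -0.2267   -0.2600 -3.33e-02 0.0002

classify_panel(tab, n_boot = 9999, seed = 2)
#>   isolate           pattern       strategy_gradual        strategy_abrupt alpha
#> 1   ISO01         no_effect      a_grow_accumulate      a_grow_accumulate  0.05
#> 2   ISO02 uniform_reduction    d_inhibited_exclude    d_inhibited_exclude  0.05
#> 3   ISO03     gradual_worse c_inhibited_accumulate c_inhibited_accumulate  0.05
#> 4   ISO04      abrupt_worse         b_grow_exclude         b_grow_exclude  0.05
```

Reading the output: ISO01 (an insensitive isolate) shows effect sizes
near zero in both arms, so neither CI excludes zero and it is called
`no_effect`.  ISO02 loses ~0.94 g dry weight under either delivery mode
with a null contrast (p ≈ 0.97): `uniform_reduction`.  ISO03's biomass
drops 0.11 g more under the ramp (p = 4e-4): `gradual_worse`; ISO04 is
the mirror case.  All four match the presets the panel was drawn from.

Schedules can be audited directly:

```r
s <- design_schedules(design)
check_equivalence(s$gradual, s$abrupt)
#> <schedule_equivalence> EQUIVALENT
#>   dose-days: 5 vs 5 (equal)
#>   final conc: 1 vs 1 mM (equal)
```

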