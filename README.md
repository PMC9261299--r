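# actage

Biological age from wearable accelerometer data, in R.

A week of minute-level intensity counts from a hip- or thigh-worn
accelerometer says a lot about how someone is aging: peak movement intensity
and the diversity of movement within each hour both decline with age, and
they decline faster in people who are aging faster. `actage` turns this
observation into a tested pipeline for NHANES-style cohorts:

1. **QC + features** — retain calibrated, complete weeks (7 × 1440 minutes,
   every day ≥ 10% nonzero minutes, age ≥ 18) and reduce each week to 336
   features: the hourly **max** and hourly **sample variance** of the minute
   counts for each of the 7 × 24 (day, hour) cells.
2. **Age model** — a random-forest regression of chronological age on the
   standardized features (70/30 age-stratified split, 500 trees,
   permutation %IncMSE importance).
3. **deltaAge** — predictions are normalized by the median prediction of
   same-age peers,
   `norm_i = raw_i / median({raw_j : age_j = age_i}) × age_i`, and
   `deltaAge_i = norm_i − age_i`. Positive deltaAge = accelerated aging.
4. **Mortality** — quartiles of deltaAge among the 60+ define
   accelerated / normal / decelerated aging classes; death proportions are
   compared with a 3-sample equality-of-proportions chi-square (df = 2, no
   continuity correction), plus per-decade and per-cause t-tests.
5. **Screens** — Pearson correlations of nutrient intake with deltaAge per
   decade-of-life bin (clustered into temporal profiles, BH-corrected
   within bins), and a Kolmogorov–Smirnov drug screen over the 70+
   population ranked by `log10(p) × sign(median shift)`.

Everything runs against a bundled synthetic-cohort generator
(`synth_cohort()`) with one latent frailty variable tying movement,
mortality, nutrients and a planted geroprotective drug together — so the
whole pipeline is testable offline, with known answers.

## Worked example

```r
library(actage)

run <- run_pipeline(run_config(
  synth = synth_config(n_participants = 1500, seed = 1),
  seed  = 1))
run
#> <actage_run>
#>   participants: 1500 input, 1500 retained after QC
#>   held-out r: 0.965 raw -> 0.971 normalized (RMSE 5.18 -> 4.79 y)
#>   death proportions (acc/norm/dec): 0.39 / 0.34 / 0.19 (p = 0.000625)
#>   top decelerating drug: DOXAZOSIN (n = 3, shift -7.1 y, KS p = 0.175)
```

Reading the output: the forest recovers chronological age on held-out
participants at r = 0.965 (synthetic data is much cleaner than real
actigraphy, where ~0.7–0.75 is typical); the peer-median normalization
straightens the fit (r = 0.971, RMSE 5.18 → 4.79 years). Among participants
aged 60+, the accelerated-aging quartile has about twice the death
proportion of the decelerated quartile (0.39 vs 0.19, chi-square
p = 6 × 10⁻⁴), and the planted geroprotector (doxazosin, whose synthetic
users move ~6 "movement-years" younger) tops the decelerating end of the
drug ranking. The planted late-peaking nutrient shows up too:

```r
dplyr::filter(run$nutrient_screen, nutrient == "DR1TFIBE")
#> fiber's correlation with deltaAge is most negative (~ -0.43) in the
#> 50-59 bin, exactly where the generator planted its peak
```

Individual stages are plain functions over tibbles and chain with the pipe —
`read_activity()` / `read_participants()` (CSV or SAS-transport XPT, NHANES
column names accepted), `qc_filter()`, `summarize_weeks()`,
`split_train_test()`, `fit_age_model()`, `predict_ages()`,
`normalize_predictions()`, `add_delta_age()`, `classify_aging()`,
`test_mortality_proportions()`, `screen_nutrients()`, `cluster_nutrients()`,
`screen_drugs()`. Results have `tidy()`/`glance()` methods and plot helpers
(`plot_predictions()`, `plot_importance_grid()`, `plot_volcano()`,
`plot_cluster_profiles()`). A thin command-line wrapper lives at
`inst/scripts/actage-pipeline.R`; YAML run configs are read by
`read_run_config()`.

See `vignettes/actage-methods.Rmd` for the model, its assumptions, what the
synthetic generator does and does not emulate, and the numerical design
choices.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
generating the default 1500-participant synthetic cohort at the given seed
and executing the full pipeline (QC → features → forest → normalization →
mortality → screens) — and writes its JSON result:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
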