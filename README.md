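# geosmoke

Tools for quantifying the relative predictive value of **temporal** versus
**location** features for self-reported smoking events captured by
smartphones — the design question behind just-in-time adaptive interventions
(JITAIs) for smoking cessation: if the clock alone predicts lapses as well
as the clock plus GPS, interventions can drop location tracking and its
privacy, battery and complexity costs.

The package is aimed at mobile-health and behavioral-epidemiology
researchers. It implements the full analysis as a reusable pipeline and,
because field datasets of this kind are access-restricted, ships a synthetic
cohort generator with *known* habit and stay-region structure so that every
stage is testable against ground truth.

## What it computes

* **Harmonization.** Each self-reported smoking time *t* becomes a closed
  half-time window [*t* − H, *t* + H], H ∈ {5, 10, 15, 20, 30} min. GPS
  fixes inside the union of windows are labeled smoking (1), others
  non-smoking (0); windows containing no fix contribute a fallback sample
  copying the nearest fix's coordinates. Temporal features per sample: the
  96 quarter-hour-bin one-hots, day of week, weekend flag, season.
* **Location representations** per participant: DBSCAN stay clusters over
  great-circle distances (eps 100 m, minPts 5; noise kept as its own
  level), K-means with silhouette-selected k, and DFI (distance from the
  initial fix).
* **Ablation grid.** Per participant, {DBSCAN, K-means, DFI} × {logistic
  regression, random forest, MLP(300, 150, ReLU, Adam)} × H × {all
  features, location excluded, time excluded}, stratified 5-fold CV,
  scored by Macro-F1 = (F1₀ + F1₁)/2.
* **Statistics.** Paired two-sided Wilcoxon signed-rank tests (exact by
  enumeration up to n = 15, midranks for ties) of all-features versus each
  ablation; Welch t-tests for subgroup characteristics; an enrollment-era
  sensitivity split at 2023-05-11; and linear mixed models (participant
  random intercepts) relating each time-of-day bin to location clusters,
  with association-rule support values.
* **Synthetic cohorts.** Smoking events follow an inhomogeneous Poisson
  process with log-intensity β_time·ĥ(t) + β_loc·ĝ(a(t)) over a simulated
  anchor-occupancy process; a redundancy knob ρ makes the occupied anchor
  an exact function of the hour (ρ = 1) or independent of it (ρ = 0).
  Defaults are calibrated to the motivating study's pre-quit data
  characteristics (≈487 fixes, ≈47 events, ≈13.65 days, ≈2.8 stay clusters
  per participant).

See `vignettes/geotemporal-ablation.Rmd` for the model, all conventions and
design decisions.

## Worked example

A small time-dominant, location-redundant cohort (habit concentration
β_time = 4, redundancy ρ = 1), one half-time interval, logistic regression:

```r
library(geosmoke)
cfg <- generator_config(n_participants = 12, beta_time = 4,
                        rho_redundancy = 1, seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic smoking cohort
#>   participants: 12 (during/post split 9/3)
#>   mean GPS fixes/participant:      84.58
#>   mean smoking events/participant: 44.92

grid <- ablation_grid(cohort, half_times = 15, families = "lr", seed = 42)
summary(grid)
#>   spatial_method family half_time_min      ALL NO_LOCATION  NO_TIME
#> 1         dbscan     lr            15 96.19477    93.05463 68.23818
#> 2            dfi     lr            15 96.48428    93.05463 57.35528
#> 3         kmeans     lr            15 96.19477    93.05463 68.23818

cmp <- compare_ablations(grid)
cmp[, c("spatial_method", "excluded", "mean_all", "mean_ablated", "p_value", "stars")]
#>   spatial_method    excluded  mean_all mean_ablated   p_value stars
#> 1         dbscan NO_LOCATION 0.9619477    0.9305463 0.1562500
#> 2         dbscan     NO_TIME 0.9619477    0.6823818 0.0078125     *
#> 3         kmeans NO_LOCATION 0.9619477    0.9305463 0.1562500
#> 4         kmeans     NO_TIME 0.9619477    0.6823818 0.0078125     *
#> 5            dfi NO_LOCATION 0.9648428    0.9305463 0.4375000
#> 6            dfi     NO_TIME 0.9648428    0.5735528 0.0078125     *
```

Reading the output: columns are mean Macro-F1 (%) across participants.
Excluding **time** costs ~28–39 points and is significant for every spatial
method (paired Wilcoxon, * = p < 0.05); excluding **location** costs ~3
points and is never significant — location is redundant with time in this
cohort by construction (ρ = 1), and the pipeline detects exactly that. The
`NO_LOCATION` column repeats across spatial methods because the
location-excluded design matrix cannot depend on the location
representation. A cohort built the opposite way (uniform habit, strong
place preference) reverses the pattern; that falsification control runs in
the test suite.

End-to-end runs with report tables (data characteristics, the ablation
grid with "mean (SD)" percent cells and significance stars, subgroup
sensitivity tables, association summaries, a config-hashed manifest):

```r
run <- run_pipeline(default_run_config(seed = 1), out_dir = "out")
```

A thin CLI wrapper is installed at `inst/cli/geosmoke.R`
(`simulate` / `run-all` subcommands).

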