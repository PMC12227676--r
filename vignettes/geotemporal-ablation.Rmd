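---
title: "Temporal versus location features for smoking-event prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal versus location features for smoking-event prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geosmoke)
```

## The scientific question

Smartphones passively provide two cheap context signals that could trigger
just-in-time support for people trying to quit smoking: the clock and the GPS
chip. geosmoke implements a complete, testable pipeline for asking how much
predictive value each signal carries for self-reported smoking events: event
streams are harmonized into labeled samples, location is summarized three
ways, a feature-ablation modeling grid is scored by Macro-F1 per participant,
ablations are compared with paired Wilcoxon signed-rank tests, and the
redundancy between time of day and place is probed directly with
mixed-effects association models.

Because the field data this design comes from are access-restricted, the
package is driven by a synthetic cohort generator with *known* temporal-habit
and location structure. Every downstream claim the package makes can
therefore be checked against ground truth, including the falsifying
direction: a cohort built to be location-dominant must reverse the headline
pattern, or the pipeline is biased.

## The generative model

Each participant owns:

* a set of 1–5 **anchor locations** (home first, others Gaussian around it,
  `anchor_spread_m` = 400 m SD);
* a **habit profile** over the 96 quarter-hour bins of the day: a mixture of
  1–4 wrapped (circular) von Mises peaks with concentration `2.5 * beta_time`;
  `beta_time = 0` collapses to the exactly uniform profile `1/96`;
* a deterministic **hour-to-anchor routine** (3-hour blocks drawn from the
  anchor preference; nights at home), and a time-independent **anchor
  preference**.

Occupancy evolves on a 5-minute step during waking hours (07:00–23:00;
smoking while asleep is not modeled, which keeps habit profiles
identifiable). At each step the participant relocates with probability
`mobility_factor * move_rate`, and additionally whenever the scheduled anchor
changes; the destination follows the routine with probability
`rho_redundancy` and the time-independent preference otherwise. So
`rho_redundancy = 1` makes the occupied anchor an exact function of the hour
(maximal mutual information between hour and place), while `rho_redundancy =
0` makes place independent of time.

A GPS fix is emitted whenever true displacement since the last emitted fix
exceeds 100 ft (0.3048 m/ft exactly) and at every smoking-report time; fixes
carry isotropic Gaussian noise (10 m SD) and a per-participant constant
privacy offset that preserves relative geometry.

Smoking events are an inhomogeneous Poisson process with intensity
proportional to

$$\lambda(t) \propto \text{base\_rate} \cdot
  \exp\{\beta_{time}\,\hat h(t) + \beta_{loc}\,\hat g(a(t))\},$$

where $\hat h$ is the z-scored habit profile at the quarter-hour bin of $t$
and $\hat g$ the z-scored preference of the occupied anchor. The exponential
modulation is normalized to unit time-average over each participant's waking
steps, so the expected event count is `base_rate × waking hours` *regardless
of the betas*; a log-normal per-participant multiplier with mean 1
(`rate_heterogeneity_sd` = 0.5) adds realistic between-person spread.
Reported times are true times plus Gaussian jitter (3 min SD — deliberately
below the smallest 5-min half-time so labeling stays mostly correct),
clipped to the observation window.

**Calibration.** Observation windows are truncated normal (mean 13.65 d, SD
3.43 d, minimum 3 d). `base_rate = 46.95/(13.65 × 16)` events per waking
hour makes the expected event count match the study the design emulates
analytically; `move_rate = 0.47` per 5-minute step was calibrated once so
that default cohorts reproduce its mean pre-quit fix count (~487 per
participant), and the 1–5 anchor range its mean DBSCAN stay-cluster count
(~2.8 at the default eps). The generated window plays the role of the
pre-quit observation period.

**What the generator does not emulate:** road-network travel (relocations
are instantaneous, one fix per arrival), weather and social covariates,
post-quit behavior change, device battery effects, and heavy-tailed
real-world fix-count distributions (the emulated study's fix-count SD was
roughly twice ours). Passing tests therefore demonstrate correctness of the
pipeline's logic and its ability to recover planted structure — not that
real cohorts behave like synthetic ones.

## Harmonization rules

All boundary conventions are fixed so that edge cases are deterministic:

* Event windows `[t − H, t + H]` are **closed**; a fix exactly on a boundary
  is smoking-labeled. Overlapping windows act through their union.
* Day bins are **half-open** `[start, end)` on local *wall-clock* minutes.
  A day always yields 96 quarter-hour (48 half-hour) bins, DST days
  included; skipped or repeated wall times map by clock reading, since the
  features of interest are wall-clock habits.
* A bin counts as overlapping a window only if the intersection has
  **strictly positive duration** (a window ending exactly at a bin start
  does not set that bin).
* The pre-quit filter is **strict** (`< quit`): a record at exactly the quit
  datetime is dropped.
* For an event window containing no fix, one **fallback sample** is created:
  coordinates copied from the fix nearest in time to the window (ties to the
  earlier fix), timestamp set to the window center (the window's own time,
  not the donor fix's, is what the temporal features should describe),
  label 1.

Two readings of "quarter-hour interval features" exist, and the package
ships both. As *predictors*, the 96 binaries are a one-hot encoding of each
sample's own bin — using bins labeled by smoking overlap as predictors would
leak the outcome. The literal per-day overlap labeling
(`interval_overlap_labels()`) is retained as its own operation and is what
the association analysis consumes.

All non-smoking fixes are kept (none are subsampled): the emulated study's
sample counts approximately equal its fix counts, which supports this
reading.

## Location representations

* **DBSCAN** over great-circle distances (haversine, R = 6371008.8 m), with
  `eps = 100 m`, `min_samples = 5`. The source design states neither value;
  100 m matches the order of the app's movement-trigger granularity and
  reproduces the target stay-cluster counts on calibrated synthetic data.
  Noise points form their own categorical level rather than being dropped —
  every sample must reach the classifier. Cluster ids follow first
  appearance, making labels deterministic.
* **K-means** on locally projected (equirectangular) planar coordinates,
  with k chosen by mean silhouette width over k = 2..10 (ties to the
  smaller k; fewer than 3 distinct points falls back to a single-cluster
  sentinel), 10 restarts under a fixed seed.
* **DFI**: great-circle distance from the participant's earliest fix.
  Degree-space Euclidean distance is available via `distance_model` for
  literal replication, but meters are the default — "straight-line
  distance" at city scale.

Cluster labels are one-hot encoded; DFI enters as a single numeric column,
z-scored per participant for standalone use and re-standardized with
training-fold statistics inside cross-validation (no leakage). Clustering
uses all pre-quit samples, not only smoking-labeled ones.

## The modeling grid

Per participant: {DBSCAN, K-means, DFI} × {LR, RF, MLP} × half-times
{5, 10, 15, 20, 30} min × {all features, location-excluded, time-excluded},
with stratified 5-fold cross-validation and Macro-F1 (unweighted mean of the
two class F1s; any 0/0 is taken as 0). Temporal features are 96 bin one-hots
+ 7 day-of-week + weekend + 4 season columns (108); the spatial block is
appended after them.

Design choices worth stating:

* **Individual-level models** are the default (the score is defined per
  participant); a pooled-cohort mode exists behind `pooled = TRUE`.
* **Folds are shared** across ablations and spatial methods for a fixed
  participant and half-time, making the Wilcoxon comparisons genuinely
  paired.
* **Location-excluded cells are computed once** per (family, half-time,
  participant) and replicated across spatial methods: the design matrix
  provably does not depend on the representation, so the repeated
  location-excluded column of the report grid is structural, and the tests
  assert the representation-independence of the matrix directly.
* Hyperparameters are fixed conventional values, all overridable: LR = ridge
  logistic regression (`glmnet`, C = 1, i.e. lambda = 1/n); RF = 100 trees,
  unlimited depth, `mtry = p/3` — the `sqrt(p)` classification default
  starves trees of the few informative columns in sparse one-hot designs and
  was measurably far worse; MLP = hidden layers (300, 150), ReLU, Adam,
  learning rate 1e-3, batch 32, 200 epochs, implemented in C++ with a
  self-contained RNG so results reproduce bit-for-bit from the seed on a
  given platform.
* Participants with fewer than 10 samples, one class, or a minority class
  smaller than the fold count are skipped with a logged reason.

## Statistics

* **Wilcoxon signed-rank**, two-sided, zeros discarded, midranks for ties;
  exact p by full enumeration of sign assignments for up to 15 retained
  pairs (valid under ties because the midrank multiset is fixed), normal
  approximation with tie correction beyond. Identical paired vectors are
  degenerate and reported as `p = NA` with a reason rather than a number.
* **Welch t-test** for subgroup characteristics (pooled-variance option for
  literal replication).
* **Enrollment-era split** at 2023-05-11, boundary day inclusive for the
  "during" group; because models are fitted per participant, subgroup
  grids are exact subsets of the full grid.
* **Time-location associations**: for each time bin (at 15- and 30-min
  widths) the binary feature "sample falls in this bin" is regressed on a
  location-cluster outcome. The default outcome coding is
  `modal_cluster_binary` (sample lies in the participant's most frequent
  smoking cluster): a linear model on arbitrary integer cluster labels is
  scale-dependent, so the literal `cluster_numeric` coding is shipped but
  never silently preferred. Pooled mode fits a linear mixed model with a
  participant random intercept by maximum likelihood (Satterthwaite
  p-values; a within-participant OLS fallback covers degenerate
  zero-residual fits); the per-participant N × M mode fits one OLS per
  participant. Bins with fewer than `min_active = 10` active stratum samples
  are skipped — they cannot support the model and dominate runtime
  otherwise. **Support** of a significant association is the
  association-rule sense: the percentage of stratum samples with the
  feature active *and* lying in the modal cluster. No multiplicity
  correction is applied by default, matching the star conventions of the
  design; Benjamini–Hochberg is available.

## Numerical and reproducibility choices

One master seed; per-participant substreams via the documented counter
scheme `(seed · 48271 + index · 9973 + stage) mod (2^31 − 1)`, so extending
a cohort never perturbs existing participants and identical configurations
give byte-identical cohort files. K-means ties, DBSCAN label order, fallback
ties and the during/post boundary are all fixed as described above. The
privacy offset is an exact coordinate translation; metric distances are
preserved only up to the cos(latitude) drift of the projection
(first-order bound `Δlat · tan(lat) · π/180` relative), which the tests
assert explicitly rather than pretending translation is an isometry.

## Validation experiments and their scale

The test suite regenerates everything from code; sizes were chosen to give
clear signal at desk scale:

* labeling versus a brute-force membership oracle on 100 random streams,
  with window nesting across half-times 5→30;
* DBSCAN versus a density-reachability oracle on random instances up to 200
  points; silhouette k-recovery on separable blobs (≥95/100 trials);
* Macro-F1 versus a confusion-identity oracle on 1000 random cases; exact
  Wilcoxon versus an independent convolution of the signed-rank null;
* a 20-participant time-dominant, fully redundant cohort
  (`beta_time = 6, rho_redundancy = 1`) run through the grid at half-times
  {10, 30} with all three families (MLP at 60 epochs at this scale): time
  exclusion must cost ≥ 10 Macro-F1 points on average and be significant at
  0.005 everywhere, location exclusion ≤ 2 points;
* the falsification control: a 12-participant location-dominant cohort
  (`beta_time = 0, rho_redundancy = 0, beta_loc = 6`, damped mobility so
  stays outlast event windows, a raised event rate so per-cluster smoking
  shares are expressible above the 0.5 decision threshold) must reverse the
  pattern;
* generator calibration over 10 default cohorts against the four target
  means (fixes, events, days, clusters), each within 3 standard errors;
* null behavior: chance-level Macro-F1 under label-independent features and
  type-I rates of both tests within 2 points of 5% over 1000 simulations.

## Known limitations

* The mobility model is a stationary renewal process over anchors —
  no trajectories, commutes, or trips outside the anchor set; DFI is
  correspondingly less informative here than it may be on real trajectories.
* Event windows smear labels across places when participants relocate
  within ±H minutes; this is faithful to the harmonization design but means
  location information degrades with mobility, a coupling worth remembering
  when interpreting ablations.
* Classification uses the 0.5 probability threshold throughout (as the
  emulated design did); under strong class imbalance Macro-F1 differences
  can understate a feature set's ranking value.
* The mixed-model association analysis treats cluster membership as a
  linear outcome; both shipped codings are documented approximations, not
  endorsements.
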