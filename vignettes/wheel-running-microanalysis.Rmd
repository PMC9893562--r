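---
title: "Wheel-running micro-analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wheel-running micro-analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(wheelmetrics)
```

## The measurement model

A home-cage running wheel (11.5 cm diameter) carries a magnet that closes a
reed switch once per revolution. Polling the switch at 10 ms yields, for
each animal-day, an ordered stream of closure timestamps at 0.01-s
resolution — the raw material of everything in this package. One closure is
one revolution, so distance is `revolutions × π × 0.115` m; no
sub-revolution correction is identifiable from the switch signal, and none
is attempted.

Running is not continuous: mice run in *bouts*. The micro-analysis
segments the stream at pauses — an inter-closure interval longer than the
pause criterion (9 s by default) ends a bout. The comparison is strict: a
gap of exactly 9.00 s stays inside the bout, which keeps the rule
deterministic at the boundary and reads the criterion as the threshold that
defines a break. From the bout decomposition, four daily metrics are
derived:

* **distance** (m/day): total revolutions × circumference;
* **number of runs** (bouts/day): a marker of the tendency to initiate
  running;
* **run length** (rev/bout) and **distance per run** (m/bout): summarized
  across a day's bouts by the *median* (configurable to the mean — whether
  the original per-day summary was mean or median is not documented, and
  day-level bout distributions are right-skewed, so the median is the safer
  default);
* **running rate** (rev/s): *pooled* — total in-bout revolutions divided by
  total in-bout duration, over multi-closure bouts only. Single-closure
  bouts have zero duration; they count toward the number of runs and
  distance but are excluded from both sides of the rate ratio, which avoids
  a division by zero without discarding the behavioral event. The pooled
  ratio, rather than a mean of per-bout rates, is robust to many tiny
  bouts; a per-bout average is available through the bout table returned by
  `segment_bouts()` if wanted.

A day with wheel access but no closures is a real observation of zero
activity and enters every downstream aggregate as zeros. A day without
wheel access (imaging, anesthesia recovery) is *missing*, represented by
file absence plus a `gaps.csv` entry, and is excluded. Because the original
records do not state which convention was used for anesthesia days, both
are supported and must be chosen explicitly (`gap_policy` in
`read_cohort_days()`); the default is `"missing"`.

## Longitudinal aggregation and cessation

Day-to-day variation in running is large (rest days, post-imaging dips), so
trajectories are analyzed as per-animal **10-day medians synchronized to the
date of birth**: half-open windows `[60,70), [70,80), …` labeled by their
centers 65, 75, …, 135 days. Days before age 60 are excluded (running
initiation is too variable), distance is followed to the 135-d bin, and the
derived metrics stop at 125 d, beyond which running is absent in the most
affected genotype. An animal that dies at age *D* contributes to no bin
centered after *D*. Group summaries are the mean ± sample SD (n − 1)
across the per-animal bin medians.

**Cessation** of running is detected per group by two-sided one-sample
t-tests of the per-animal bin medians of daily distance against zero, in
ascending age; the first bin whose test is not significant (default
α = 0.05) is the cessation bin. Two degenerate cases are decided without a
t-test: a bin in which every animal's median is exactly zero is
non-significant (SD = 0, nothing to test), and a bin of identical positive
values is significant. Per-animal medians — not raw daily values — are
tested, matching the aggregation unit of the rest of the longitudinal
layer. Since a 10-day bin cannot localize cessation to a day,
`interpolate_cessation_day()` additionally interpolates the group mean
trajectory linearly to its zero crossing; this is offered as a
complementary day-resolution estimate, not asserted as the original
procedure, which is not described at day resolution.

## Linking behavior to biomarkers

Disease biomarkers (aerated/tissue/total lung volume by micro-CT, talus
bone volume, subchondral trabecular metrics) arrive as a tidy longitudinal
panel keyed by experimental unit × timepoint. The unit is the **animal**
for lung measures and the **individual limb** for joint measures, because
inflammatory-erosive arthritis is strongly asymmetric. The statistics
layer implements:

* `percent_change_from_baseline()`: joint endpoints as
  `100 × (v_t − v_2mo) / v_2mo`;
* `log_transform_metric()`: running metrics are right-skewed with exact
  zeros after cessation, so the normalizing transform is `log10(x + 1)` —
  the offset keeps terminal zeros in the analysis, and base 10 makes the
  scale readable (0 → 0, 9 → 1, 999 → 3);
* `change_since_first()`: within-unit change from the first observation,
  which removes between-animal level differences before regression;
* `factorial_mixed_effects()`: a REML linear mixed model with all main
  effects and interactions of the supplied factors (genotype,
  sex or activity, categorical time), a random intercept per unit, and
  Wald chi-square tests per term under sum-to-zero contrasts. With a
  single timepoint it degrades to a fixed-effects factorial ANOVA. A
  singular random-effect fit is reported with a warning, never silently
  ignored.
* `partial_correlation_longitudinal()`: the headline association
  statistic. Each variable is fit with a mixed model having **time
  (categorical) as the only fixed effect** and a random intercept per
  unit; the partial correlation is the Pearson correlation of the paired
  conditional residuals (observed − time effect − unit intercept). The
  p-value uses a t statistic on `n_obs − 2 − (n_time − 1)` degrees of
  freedom, deducting the time fixed-effect dimension; Satterthwaite-style
  corrections are out of scope. Because the estimator originally used for
  these correlations is not fully specified, a second estimator is exposed
  (`method = "rmcorr"`): time-detrend both variables, then extract the
  common within-unit association by ANCOVA on unit (the repeated-measures
  correlation), with `n_obs − n_units − 1 − (n_time − 1)` df. The two
  agree closely on the simulated panels (see the association tests); the
  conditional-residual method is the default because it mirrors the
  stated model most directly.

Time is categorical throughout (imaging months / bin centers), not
continuous. No multiple-testing adjustment is applied to the
correlation table — pairs are reported with unadjusted p-values, which the
user should keep in mind when scanning many metric × measure pairs.

## The cage simulator

No animal data ship with this package; the simulator generates cohorts
with the statistical structure the analysis assumes, so every stage can be
validated by parameter recovery.

**Presets.** `group_presets()` encodes one row per genotype × sex stratum
of the running arm (9 + 9 + 12 + 14 = 44 animals), parameterized by the
group start (65 d) and end (135 d) values of the four metrics, e.g. WT
females 8703.3 → 7472.8 m/day and TNF-Tg females 2660.1 m/day declining to
cessation at 113 d (males: 140 d). Every parameter interpolates linearly
between its 65-d and 135-d anchors; distance is forced to a hard zero
after the cessation age. The TNF-Tg female end-of-window value is set to 0
(rather than the small positive straggler mean observed at 135 d) so that
the configured cessation age is an exact generator truth. Mortality
censoring is emulated by per-animal death ages in the preset (five TNF-Tg
females and one WT female lost before endpoint; the specific ages are a
convention chosen near the end of the window, as only the counts are
known).

**One night.** `simulate_night()` draws a daily distance target, converts
it to revolutions, draws a Poisson number of bouts, spreads revolutions
over bouts by a symmetric multinomial (each bout gets at least one; if
fewer revolutions than bouts are available the bout count yields —
distance is the primary quantity and wins every conflict), gives
within-bout inter-closure intervals of `1/rate` with ±20% uniform jitter,
and places bouts in the 00:00–12:00 dark window with all inter-bout gaps
forced above 9 s. Three numerical guards matter:

* the within-bout interval is capped at 7 s so the jittered maximum
  (8.4 s) stays below the 9-s criterion — otherwise a slow preset would
  shatter its bouts; this floors the *realized* rate at ≈0.14 rev/s when a
  preset's configured rate falls below that late in disease;
* daily distance is drawn from a normal truncated at zero with the
  configured value as its (truncation-free) median; when the configured SD
  exceeds the median — terminal disease, mostly-zero days with rare
  bursts — the draw switches to a zero-inflated exponential (zero
  probability 0.4, exponential calibrated so the marginal median equals
  the configured median);
* a night is finite: draws whose revolution demand exceeds the dark
  window's physical capacity at the configured rate are truncated at
  capacity, which leaves medians (the reported statistic) untouched; a
  preset whose *median* demand does not fit is a configuration error and
  raises the infeasible-packing error.

Reproducibility uses a single root seed with per-animal child seeds
derived as `(seed × 1000003 + index × 7919) mod (2^31 − 1)`, so cohorts
are reproducible animal-by-animal and a cohort directory is byte-identical
across runs of the same seed.

**Biomarker links.** `simulate_biomarkers()` generates, for a
`link_presets()` row, a running series and a biomarker series whose
coupling is the *configured partial correlation on the estimator's own
scale*: the running metric is generated (lognormal noise around the
stratum trajectory), pushed through the actual analysis transforms
(log, change-since-first, mixed-model detrending), and the biomarker's
residual is built jointly with those residuals as
`ρ·r_x + √(1−ρ²)·z` on top of a time trend and unit intercept. This makes
the configured ρ an exact generator truth for the quantity the estimator
measures, so recovery bias isolates estimation error (re-estimated trends
and BLUP shrinkage on the biomarker side) rather than transform
distortion. The configured ρ values are the published
running–biomarker partial correlations (e.g. TNF-Tg female talus–distance
−0.614, WT female aerated-lung–distance 0.705); biomarker trends and
variance components are conventions on the plausible scale of each
measure.

**What the simulator does not emulate.** Summary statistics only: no
circadian harmonics or ultradian structure within the night, no
autocorrelation between days, no pain model, no light-phase running
(real mice do a little; the generator places 100% of closures in the dark
window, comfortably satisfying the night-locked pattern), and the
behavioral metrics are co-generated but reconciled to distance rather than
jointly calibrated — the four published metrics are arithmetically
interdependent and cannot all be matched simultaneously. Passing
recovery tests therefore demonstrates that the *pipeline* is correct under
the declared generative assumptions, not that those assumptions exhaust
real cage data.

## Validation problem sizes

The test suite validates segmentation against an independent
closure-by-closure oracle on 1000 random streams; recovers the four
baseline group parameters through the full event-stream pipeline with
9 animals × 20 seeds per target (10–15 days per animal around the first
analysis bin); recovers the two configured link correlations with
100 units × 4 timepoints × 100 seeds; calibrates the null rejection rate
over 500 simulated panels; and round-trips a configured cessation age over
100 seeded cohorts. These sizes put Monte-Carlo error comfortably inside
each tolerance (5% for behavioral parameters, ±0.10 for correlations)
while the whole suite runs in minutes on a single core.

## Known limitations

* The 9-s pause criterion, bin layout, and analysis windows are
  configurable but default to the published design; other designs (e.g.
  different light cycles) need a phase offset the event layer does not yet
  expose — timestamps are assumed dark-cycle-aligned at midnight.
* The conditional-residual partial correlation treats its df heuristically
  (fixed-effect dimension only); with few units its p-values are
  approximate. The null calibration shows the rejection rate is near
  nominal at 100 units × 4 timepoints.
* `factorial_mixed_effects()` reports Wald chi-square tests; it does not
  reproduce repeated-measures ANOVA F statistics with sphericity
  corrections, so p-values on small samples will differ from those of
  GUI statistics packages.
* Cessation is reported at bin resolution; the interpolation refinement
  assumes local linearity of the group mean trajectory.
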