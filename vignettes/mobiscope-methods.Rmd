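---
title: "mobiscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mobiscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Real-life mobility in community-dwelling older adults has two distinct
faces. *Physical-activity-based mobility* is how much the body moves:
here, daily Active-&-Gait Time (AGT, hours of gait or active bouts above
3 METs) and daily step counts, both derived from classified inertial-
sensor intervals worn on a smartphone. *Life-space mobility* is how far a
person ranges through the environment, including passive transport: here,
the daily convex-hull area of GPS fixes (km²), daily travelled distance
(km) and the maximum action range (AR-max, the largest straight-line
distance from home over the monitoring period, km). mobiscope computes
these five outcomes from raw fix/interval streams, applies the
quality-control rules appropriate to free-living smartphone data, and runs
the association analysis that relates them to multi-domain covariates
(demographic, environmental, physical, cognitive, psychological, social).

## Mobility metrics and their quality-control rules

**Activity outcomes.** Intervals are clipped to a 07:00–21:00 local-time
window (steps prorated linearly when a bout is cut — the only
assumption-free choice); a day is valid only with ≥ 9 h of registration
(boundary inclusive); daily AGT is the summed duration of gait/active
bouts *strictly* above 3 METs (a 3.0-MET bout contributes nothing — "more
than 3" read literally); daily values are scaled to a nominal 12-h day as
`value × 12 / registration_hours` and averaged over valid days.
Registration hours are the union of interval durations (non-overlap is
enforced at parse), not the wall-clock span.

**GPS outcomes.** Fixes beyond 15 km of home are removed first
(habitual-mobility filter; boundary inclusive — immaterial in practice but
fixed for reproducibility), and all metrics are computed afterwards.
Daily life-space area is the convex-hull area of the day's fixes
(`grDevices::chull` vertices + shoelace) on a local azimuthal-equidistant
plane centred at the participant's *home*, not the daily centroid: one
frame per participant keeps days comparable, and the projection preserves
distances from home exactly. Days with fewer than three distinct fixes
have an *undefined* (missing) area, not zero, so GPS-dropout days cannot
deflate a participant's average; three or more collinear fixes give 0.
Daily distance is cumulative path length (sum of consecutive-fix
great-circle distances); this is the only reading consistent with daily
totals in the tens of km for an urban cohort, but "net displacement"
(first-to-last fix) is exposed via `distance_mode = "net"`. AR-max is a
period maximum, not a daily average. Whether daily hulls were meant to be
computed before or after the 15-km filter is not decidable from the
method's description; filter-first is used, matching the stated intent of
excluding exceptional trips from *the analysis*.

All spherical computations use a sphere of radius 6371.0088 km. Versus
ellipsoidal geodesics the error is far below 0.5% at the 15-km scale (the
test suite bounds planar-hull vs geodesic-polygon area discrepancy at
0.5% with an l'Huilier spherical-excess oracle). No GPS-noise or speed
filtering is applied by default (the metric definitions mention none); an
optional `filter_max_speed()` gate (default 200 km/h) exists for real
data. Home is a required input; `estimate_home()` (medoid of daily first
fixes) is provided but never applied implicitly.

## The statistical chain

`run_association_analysis()` executes, in order: square-root transforms of
the three life-space outcomes (right-skewed on their natural scales) →
KS normality screening → Tukey outlier screening → Little's MCAR test →
mean imputation → Spearman screening → per-outcome stepwise regression
with diagnostics. Choices a maintainer should know about:

* **"F = 0.05 for entry, F = 0.10 for removal"** is interpreted as
  *probability-of-F* thresholds (the SPSS convention). F-statistic cutoffs
  of 0.05/0.10 would be nonsensical (essentially everything would enter).
* **Tukey screening** flags values strictly outside
  `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` with type-7 (linear-interpolation)
  quartiles, R's default; no quartile rule is canonical for Tukey fences,
  so the ambient platform's is used and pinned by oracle tests. Flagged
  *cells* are set missing and then mean-imputed (`outlier_mode = "cell"`),
  which keeps n intact — the only reading compatible with removing ~1% of
  values yet reporting complete-n models; whole-row deletion is available
  as `outlier_mode = "case"`.
* **Mean imputation** leaves every column mean unchanged and shrinks
  variance monotonically with the missing rate (both property-tested).
  Little's MCAR test (EM-estimated grand mean/covariance; chi-square over
  missingness-pattern means, `df = Σ p_j − p`) is run on the
  *pre-imputation* mask to justify the imputation; with no missing cells
  it degenerates to statistic 0, p = 1, and says so.
* **KS normality** uses the Lilliefors correction, since mean and SD are
  estimated from the sample (the uncorrected test would be wildly
  conservative); p-values come from the Dallal–Wilkinson approximation
  with Stephens' upper-tail modification, the standard Lilliefors
  implementation. Calibration was verified by simulation: the true level
  at nominal α = 0.10 is ≈ 0.103–0.108 for n between 100 and 1000
  (10,000–20,000-replicate runs). The acceptance test draws 1000
  observations per replicate, the size at which this operation's contract
  is stated. The normality screen is *descriptive* (recorded in the
  report); it does not gate the analysis.
* **Spearman** is the Pearson correlation of mid-ranks (average ranks on
  ties) with a two-sided t-approximation p-value on n − 2 df — standard at
  cohort sizes near 100; an exact-permutation oracle backs it for tiny n
  in the tests. No multiplicity correction is applied by default,
  mirroring common screening practice (and its false-positive risk); a
  Benjamini–Hochberg option exists (`adjust_correlations = "BH"`).
* **Stepwise regression** enters the candidate with the smallest
  partial-F p-value while it is below `p_enter`, then removes (worst
  first) any included variable whose p-value exceeds `p_remove`.
  Termination is guaranteed by a model-state cycle guard: a step that
  would recreate a previously visited model is refused and logged. The
  final model is refit on z-scored outcome and predictors, so coefficients
  are standardized betas; adjusted R², per-coefficient p, the maximum VIF
  and the Shapiro–Wilk residual p (Royston AS R94, via
  `stats::shapiro.test`) are reported with the full entry/removal trace.
  At termination every retained variable has p ≤ `p_remove` and no
  excluded candidate would enter — both property-tested.
* Gender and education enter as numeric codes, exactly as such covariate
  tables are usually correlated; no categorical machinery is applied.

## The synthetic cohort: a stated world

The generator exists so that every stage has a testable ground truth. Its
defaults are fixed once, as the package's stated world, and are *not*
tuning knobs:

* **Cohort**: 150 participants, 6–9 registration days each with ~83%
  having exactly 7 (the typical completion pattern of a one-week
  protocol), homes uniform in an 8-km disc around central Cologne.
* **Covariates**: 12 variables across six domains, multivariate normal
  with instrument-scale means/SDs (e.g. grip strength 282 ± 113 N, leg
  strength 1.45 ± 0.45 kg/kg, gait speed 1.38 ± 0.15 m/s, daily maximum
  temperature 21.5 ± 3.7 °C) and a modest positive-definite correlation
  structure (strength measures intercorrelated and declining with age;
  women lower grip strength). Gender/education are continuous codes — a
  deliberate infidelity: the pipeline treats them numerically anyway.
* **Outcome model**: each outcome is linear *on the square-root scale* in
  z-scored covariates plus Gaussian noise, truncated at zero before
  squaring, AR-max capped at 15 km so the home filter is non-binding on
  clean data. This makes the analysis chain exactly well-specified, so
  recovery tests have a truth. Standardized effects follow the
  low-to-moderate pattern typical of this literature (age and strength on
  activity outcomes, grip strength on life-space outcomes, |β| ≈ 0.2–0.3),
  with noise set so that true model R² is low (≈ 0.05–0.15). The
  `distance` outcome's effects are package-invented (no canonical
  published structure; it is excluded from default modelling and reported
  as a metric only).
* **Day-level variability**: a mean-one lognormal multiplier
  (`day_sdlog = 0.25`) on each day's targets. No distributional guidance
  exists for within-person day-to-day variation; lognormal keeps targets
  positive and ~25% day-to-day scatter is what free-living step-count data
  typically show. This is a free choice, made once.
* **Tracks**: home-anchored out-and-back *radial* polyline trips on the
  local plane, ~1-min fix spacing. Radial legs through the projection
  centre are geodesics, so the farthest waypoint realizes AR-max exactly
  and path length is exact; a perpendicular trip turns the hull into a
  triangle of exactly the area target (feasibility-clipped to `ar²/2`,
  with the realized value recorded in `truth.json`); filler trips pad the
  path length to the distance target (so realized distance is
  `max(target, geometric minimum)`). Activity days carry integer-second
  bouts summing exactly to the AGT/step targets, 12 h of registration by
  default (making scaled = raw, so day targets are exact on both scales).
* **Contamination**: MCAR cell missingness at 3% (MAR/MNAR mechanisms are
  provided to test the MCAR test's power, not as defaults) and gross
  outliers (±8 SD) in 0.88% of covariate cells.

What a green test does *not* establish: nothing here resembles real human
trajectories (no road network, transport modes, GPS noise, indoor dropout,
or multi-anchor days), real activity microstructure (bout lengths, MET
distributions), or real covariate marginals (no skew, no categorical
structure). Fidelity is to the *statistical structure the pipeline
assumes* — which is precisely what makes parameter recovery a meaningful
test of the pipeline rather than of the generator.

## Numerical notes

* EM for the incomplete-data normal model is grouped by missingness
  pattern, ML covariance (divisor n), tolerance 1e−6, 200-iteration cap;
  an indefinite pairwise-complete start falls back to a diagonal start.
  Little's statistic inherits ML estimates, per its standard definition.
  The test is asymptotic: simulation shows nominal level at a few hundred
  rows (0.050 at n = 300, 500 replicates) and mild over-rejection below
  ~100 rows.
* `stepwise_regression` refuses constant candidates and missing values
  (handling them is the chain's job, not the solver's); a constant
  outcome is an error.
* `vif()` computes auxiliary R² by pivoted-QR projection, so duplicated
  columns elsewhere in the design flag only the truly collinear
  predictors as infinite.
* Quantities written to reports go through `jsonlite` at full precision;
  report files are pure functions of bundle + configuration (byte-identical
  across re-runs), with wall-clock timestamps confined to the run log.

## Known limitations

* Spherical-earth geometry: adequate within the 15-km analysis radius by
  construction; do not reuse `haversine_km` paths for continental-scale
  work where ellipsoidal error matters.
* The Lilliefors p-value is an analytic approximation (true level ≈ 0.105
  at α = 0.10); exact Monte-Carlo calibration per call was judged not
  worth the runtime for a descriptive screen.
* Stepwise selection inherits all the classical caveats (post-selection
  inference, instability of the selected set near the threshold); the
  package reports the trace so users can see near-misses.
* The local-time handling assumes each interval/fix carries an explicit
  UTC offset and treats "local wall-clock time" as offset-shifted UTC; DST
  transitions inside a single day are therefore resolved by whatever
  offsets the device stamped, not by a timezone database.
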