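---
title: "Methods: quantifying colony-level spatial segregation and fisheries overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying colony-level spatial segregation and fisheries overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albatrack)
library(dplyr)
```

`albatrack` implements the analysis chain used to ask whether two nearby
seabird breeding colonies partition the ocean between them, and what that
partitioning implies for their relative exposure to fishing fleets. The
motivating system is a pair of wandering-albatross colonies in the South
Georgia archipelago about 42 km apart — a trivial distance relative to
foraging ranges that reach 2000 km and more — with contrasting population
trajectories. The package provides every stage as a testable function:
synthetic data generation, track cleaning, trip segmentation, kernel
utilization distributions (UDs), a randomization test of segregation,
circular statistics for wind and departure bearings, a gridded
fisheries-overlap index, and data preparation for habitat models.

## The trip as the unit of analysis

Breeding albatrosses are central-place foragers: every foraging excursion
starts and ends at the colony. All inference in the package is built on
*trips*:

1. **Speed filter.** Fixes implying travel faster than 80 km/h from the
   previously retained fix are removed, sequentially per bird. The
   sequential (root-removal) form matters: a single displaced fix makes
   *two* consecutive speeds implausible, and a pairwise rule would delete
   the innocent neighbour as well. The synthetic generator injects
   displaced fixes with known labels, so the tests can require exact
   recovery.
2. **Regularization.** Linear interpolation of latitude and longitude onto
   whole-hour marks, per bird. Gaps longer than 12 h (configurable) are
   not interpolated across, except where a mark coincides exactly with a
   raw fix. Hourly fixes make fix counts proportional to time, which the
   fisheries overlap index relies on.
3. **Trip splitting.** A trip runs from the last fix inside the colony
   buffer before an excursion to the first fix back inside. The buffer
   radius defaults to 5 km: small enough to exclude foraging, large
   enough to absorb location error at the colony. Excursions shorter than
   6 h are discarded as near-colony loafing (the shortest stage-mean trips
   are ~73 h, so this is conservative); a terminal excursion with no
   return is kept but flagged incomplete, and incomplete trips are
   excluded from summary statistics because they are truncated at an
   arbitrary point.
4. **Stage inference.** The breeding season is divided into three windows
   (incubation 9 Jan–29 Mar, brood guard 2 Mar–18 Apr, postguard
   5 Apr–18 Aug; half-open at UTC midnight). The windows overlap, and
   where a trip's span is consistent with two stages the post-trip colony
   attendance decides: more than 12 h at the nest points to the earlier
   stage. The rule reflects nest-relief behaviour — incubating and
   brooding birds sit for long spells after relief, whereas postguard
   birds make brief feeding visits. For a bird's last observed trip the
   attendance is unknown and the later stage is assigned; a consequence
   worth knowing is that trips in the March overlap zone with long
   attendance are classified as incubation even if the chick has just
   hatched, which is exactly the ambiguity the real protocol faces.

## Utilization distributions and the segregation test

Fixes are projected into an azimuthal equidistant plane centred on the
colony region. This projection preserves distance and bearing from its
centre exactly, so kernel bandwidths expressed in km mean what they say
in the region where the kernels live; the round trip through the inverse
projection is sub-metre over the whole foraging range.

Each trip's UD is an isotropic bivariate Gaussian kernel density with a
stage-specific smoothing parameter (SD 105 km for incubation and
postguard, 60 km for brood guard) evaluated on a shared 10-km grid and
normalized to sum to one. The kernel SD, in km, is the natural reading of
those smoothing parameters on a kilometre grid. Population UDs are the
unweighted mean of trip UDs, renormalized; the trip — not the bird — is
the aggregation unit because the trip is also the exchangeable unit in
the randomization test. (Unequal trip counts per bird therefore weight
the population surface; that is a property of the estimand, not a bug.)

Overlap between two UDs is Bhattacharyya's affinity,
$BA = \sum_{cells} \sqrt{p_A \, p_B} \in [0, 1]$. The segregation test
reassigns whole trips to the two colonies at random, preserving group
sizes, and recomputes the population UDs and BA each time; the p-value is
the plain proportion of randomized affinities *smaller* than the observed
one (1000 iterations by default). The plain proportion is deliberate — it
is the published rule — and the usual $(b+1)/(n+1)$ variant is available
via `plus_one = TRUE`. Because the trip UDs are computed once and reused,
the null is vectorized as permutation-indicator matrices against the
trip-by-cell matrix, which is what makes 200-iteration calibration runs
over hundreds of replicates affordable.

Core foraging areas (50%) and home ranges (95%) are minimal top-density
cell sets: cells sorted by density, stable tie-break on cell index, the
shortest prefix reaching the level. Reported affinities can be restricted
to an isopleth by renormalizing each UD within its own top-density set
before the affinity sum — the chosen interpretation of comparing "core
areas" rather than whole surfaces, since no exact restriction rule is
standard.

**Representativeness.** Whether a sample of trips captures the population
core is assessed by subsampling: for each subsample size draw random trip
subsets, and score the fraction of the left-out trips' fixes that fall in
the subset's 50% isopleth. The mean inclusion curve is fit with a
saturating hyperbola $y = a\,s/(b+s)$ — a deliberately simple asymptote
model — and the statistic is the fitted inclusion at the full sample size
as a percentage of the asymptote $a$, capped at 100. With fewer than
three subsample sizes no asymptote is identifiable; the raw inclusion is
returned with a low-confidence flag.

## Wind and circular statistics

Wind is handled in the meteorological "from" convention (a southwesterly
wind blows *from* 225°); reanalysis u/v components are "toward"
components, hence the 180° flip in `uv_to_wind()`. All angles are degrees
in [0, 360) at the interface and radians internally.

- `circular_mean_sd()` reports the vector-resultant mean direction and
  the circular SD $\sqrt{-2\ln R}$.
- `watson_u2()` is Watson's two-sample U² from the pooled empirical CDFs,
  with tie multiplicities integrated against the pooled measure so that
  identical samples give exactly 0. The p-value is by label permutation
  (seeded); a banded report against the asymptotic critical values
  (0.152, 0.187, 0.268 for the 10%, 5%, 1% levels) reproduces the
  "p > 0.10" reporting style.
- Circular regressions model the response direction as von Mises with
  mean $\mu + 2\arctan(\eta)$, where $\eta$ is $\beta_c \cos x +
  \beta_s \sin x$ for an angular predictor or $\beta z$ for a centred,
  scaled linear predictor. Estimation is maximum likelihood (BFGS from a
  mean-direction start, tolerance 1e-10 on the relative likelihood);
  per-component p-values are likelihood-ratio tests by default, with a
  seeded permutation option. The tangent link bounds the angular offset
  in $(-\pi, \pi)$, which keeps the likelihood well behaved; the exact
  estimator behind published cos/sin component p-values is not uniquely
  determined, and this von Mises ML formulation is the package's
  interpretation, validated by its own null calibration and power tests.

Departure bearing is the circular mean of step headings over the first
3 h at sea, skipping zero-length steps.

## The fisheries overlap index

Fishing effort arrives as hours fished per 1° cell, keyed by flag state,
gear type and breeding stage. Cells are half-open bins $[k, k+1)$ in both
axes (boundary fixes fall in the lower-left cell). For each colony and
stage window, the proportion of regularized fix time per cell is
multiplied by the hours fished there and summed:

$$\mathrm{index} = \sum_{cells} \text{(share of colony time)} \times
\text{(hours fished)}.$$

The index is a relative exposure measure, not a bycatch rate. It is
linear in effort and additive over cell partitions, which the tests
verify against brute-force summation, and the "all fishing" rows
reconcile exactly with the gear/flag disaggregation. Because the stage
windows differ in length (and overlap — a fix can legitimately count in
two stages), indices compare between colonies within a stage, never
between stages; the output carries that caveat as an attribute.

## Habitat-model data preparation

The package prepares inputs for presence/background habitat models but
deliberately stops short of fitting smoothers (standard GAM machinery
does that). Pseudoabsences are drawn uniformly *by area* on the spherical
cap within the maximum observed foraging range of the colony — cosine of
the angular distance uniform on $[\cos\theta_{max}, 1]$ — at exactly
three per presence, per colony and stage. Eddy kinetic energy and
chlorophyll a are log10-transformed and the SD of sea-surface temperature
square-root-transformed; non-positive values in a log target are an
error, not a silent drop. Collinearity screening visits covariates in
order of predictive rank and keeps one only if |Pearson r| ≤ 0.6 against
everything already kept, making the result order-independent. AUC is the
tie-averaged rank estimator with the conventional bands (0.5–0.7 poor,
0.7–0.9 reasonable, >0.9 very good), and cross-validation folds are
assigned per bird so validation is between individuals.

## The synthetic-data generator

The generator exists so the whole chain can be exercised and calibrated
without any tracking data. Its defaults encode the study conditions the
package is built around: two colonies 42 km apart; hourly fixes; trip
counts per colony and stage of 17/26/34 and 25/44/118; log-normal trip
durations with stage medians of 300, 75 and 160 h; outbound ground
speeds around 25 km/h (so ranges reach hundreds to ~2000 km); departure
bearings from colony-specific von Mises mixtures, westerly-only at one
colony and a 60/40 west/east mixture at the other; predominantly
southwesterly winds (mean from-direction 225°, concentration 1.5, speeds
9 ± 3 m/s); and fishing effort clustered in gear- and flag-specific
hotspots on the Patagonian Shelf and east of the archipelago. Where the
motivating system prescribes no value (trip shape, attendance
distributions, hotspot geometry) the defaults are chosen once as
field-realistic: a three-phase trip (correlated outbound walk along the
departure bearing, slower and more tortuous foraging, direct homing with
bearing jitter), and log-normal attendance with medians of 30/24/8 h by
stage, reflecting long nest-relief sits early in the season and brief
postguard feeding visits.

Outliers are injected by displacing single interior fixes 250 km, so the
80-km/h filter has exact ground truth. All departure times sit on the
hourly lattice, as interpolated tracking data would. Everything is
deterministic given `(config, seed)`.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: ARGOS error ellipses and irregular duty
cycles, wind-dependent flight mechanics, area-restricted search driven by
real prey fields, device failure, and spatial covariance between effort
hotspots and bird habitat. The generator validates the statistical
machinery, not the ecology.

## Numerical choices and problem sizes

- Spherical geometry uses the 6371.0088 km mean Earth radius throughout;
  distances are haversine, bearings great-circle forward azimuths.
- UD grids in the package's own test and acceptance runs use 25–50 km
  cells with 60–105 km kernels and trips of tens of hours; these sizes
  were chosen so that calibration experiments (hundreds of replicates of
  a 100-trip, 200-iteration randomization test) complete in minutes while
  leaving the kernel comfortably wider than the cell. The 10-km default
  cell matches the motivating analysis and is what a real-data user
  should keep.
- The randomization p-value with `n_iter` below 100 triggers a warning
  (the plain proportion is then unstable, and can be exactly 0).
- Degenerate inputs fail loudly: a bearing at the exact colony position
  is an error rather than a silent 0°, antipodal circular means are
  flagged undefined, empty stage windows warn and return empty grids.
- Type-I error of the segregation test is checked empirically (rejection
  at the 5% level within [0.02, 0.08] over 200 null replicates), and its
  power against a 180° east/west bearing contrast exceeds 90%; Watson's
  U² and the circular regressions carry analogous null-calibration and
  power checks. These are properties of the implementation verified at
  the scaled-down sizes above, not claims about any particular dataset.

## Known limitations

- Trip splitting assumes the colony buffer is crossed cleanly; a bird
  loitering exactly at the buffer edge can fragment a trip. The 6-h
  minimum absorbs most of this.
- The representativeness asymptote is a two-parameter hyperbola; samples
  whose inclusion curve saturates very early can fit `b` poorly, though
  the reported percentage is insensitive to that once inclusion is near
  its ceiling.
- BA restricted to an isopleth depends on the restriction convention
  (each UD renormalized within its own top-density set); other
  conventions (shared mask, no renormalization) give different numbers.
- The overlap index inherits every bias of the effort data (AIS coverage,
  disabled transponders); it ranks exposure, it does not estimate
  mortality.
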