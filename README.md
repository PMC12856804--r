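# albatrack

Quantifying at-sea spatial segregation between seabird breeding colonies —
and what it means for their exposure to fisheries.

Colonies of wide-ranging central-place foragers that sit only tens of
kilometres apart can nevertheless partition an ocean basin between them.
When they do, birds from the two colonies meet different fishing fleets,
face different bycatch risk, and their populations can diverge.
`albatrack` implements the full analysis chain for tracking data from two
such colonies (the motivating system is a pair of wandering-albatross
colonies in the South Georgia archipelago, ~42 km apart, with foraging
ranges up to ~2000 km):

- **Trip processing** — an 80 km/h speed filter with sequential root
  removal, regularization to hourly fixes, colony-anchored trip
  splitting, breeding-stage inference from calendar windows and colony
  attendance, and per-trip summary statistics (duration, total distance,
  foraging range, bearing to the farthest point).
- **Spatial segregation** — kernel utilization distributions (UDs) on a
  shared planar grid with stage-specific smoothing (105 / 60 / 105 km),
  50% core and 95% home-range isopleths, Bhattacharyya affinity
  `BA = Σ √(p_A p_B)`, and a trip-randomization test: trips are randomly
  reassigned to colonies and the p-value is the proportion of randomized
  affinities smaller than the observed one. Sample representativeness is
  assessed by a subsampling-inclusion bootstrap with a saturating
  asymptote fit.
- **Wind circular statistics** — meteorological u/v conversion, circular
  mean/SD, Watson's two-sample U² homogeneity test (permutation or banded
  p-values), departure bearings over the first 3 h at sea, and von Mises
  circular-circular / circular-linear regressions with likelihood-ratio
  or permutation component tests.
- **Fisheries overlap** — per 1° cell, the proportion of colony time is
  multiplied by the hours fished there and summed, disaggregated by
  breeding stage, gear type and flag state; a relative exposure index,
  not a bycatch rate.
- **Habitat-model preparation** — area-uniform pseudoabsences (3 : 1)
  within the maximum foraging range, log₁₀/√ covariate transforms,
  rank-priority collinearity screening at |r| > 0.6, grouped-by-bird CV
  folds and tie-averaged AUC with the conventional performance bands.
- **A seeded synthetic-data generator** whose defaults encode the study
  conditions above (two colonies, hourly fixes, colony-specific
  departure-bearing mixtures, southwesterly winds, clustered effort
  hotspots, labelled outlier fixes), so every stage of the pipeline is
  testable end to end without any tracking data.

Everything is tidyverse-native: functions take a data frame first and
return tibbles, fitted objects have `tidy()`/`glance()` methods, and the
result types have `autoplot()` methods.

## Worked example

Simulate one brood-guard season for two colonies (25 trips each), clean
and split the tracks, and test for segregation:

```r
library(albatrack)
library(dplyr)

cfg <- sim_config(
  birds_per_colony = c(bird_island = 10, prion_island = 10),
  trips_per_stage = tibble::tibble(
    colony = rep(c("bird_island", "prion_island"), each = 3),
    stage = rep(c("incubation", "brood_guard", "postguard"), 2),
    n_trips = c(0, 25, 0, 0, 25, 0)),
  trip_durations = tibble::tibble(
    stage = c("incubation", "brood_guard", "postguard"),
    median_h = 30, sigma = 0.3))

tracks <- simulate_tracks(cfg, seed = 42)
clean <- tracks |> speed_filter() |> regularize()

cols <- default_colonies()
trips_bird  <- clean |> filter(colony == "bird_island")  |>
  split_trips(cols[1, ]) |> infer_stage()
trips_prion <- clean |> filter(colony == "prion_island") |>
  split_trips(cols[2, ]) |> infer_stage()

metrics <- bind_rows(trip_metrics(trips_bird, cols[1, ]),
                     trip_metrics(trips_prion, cols[2, ]))
metrics |>
  group_by(colony) |>
  summarise(n_trips = n(), duration_h = mean(duration_h),
            range_km = mean(foraging_range_km),
            bearing_deg = circular_mean_sd(bearing_far_deg)$mean_deg)
#> # A tibble: 2 × 5
#>   colony       n_trips duration_h range_km bearing_deg
#>   <chr>          <int>      <dbl>    <dbl>       <dbl>
#> 1 bird_island       25       30.3     305.       276.
#> 2 prion_island      25       33.4     346.        12.6
```

Both colonies make ~30 h trips of ~300 km range, but their mean bearings
differ (the generator's defaults send one colony west only and split the
other between west and east). The randomization test asks whether the
observed UD overlap is smaller than expected if trips were exchangeable
between colonies:

```r
segregation_test(trips_bird, trips_prion, bw_km = 60, cell_km = 25,
                 n_iter = 500, seed = 42)
#> Trip-randomization segregation test
#>   groups: 25 vs 25 trips;  500 randomizations (seed 42)
#>   observed BA = 0.7536;  null mean = 0.9280;  p = 0
```

Observed affinity 0.75 against a null centred at 0.93: none of the 500
random reassignments produced overlap that low, so the colonies are
significantly segregated. Downstream, that asymmetry translates into
unequal fisheries exposure:

```r
eff <- simulate_effort(cfg, seed = 42)
overlap_by_group(clean, eff) |> filter(gear == "all", stage == "total")
#> # A tibble: 2 × 5
#>   colony       stage gear  flag  index
#>   <chr>        <chr> <chr> <chr> <dbl>
#> 1 bird_island  total all   all    405.
#> 2 prion_island total all   all    315.
```

The effort hotspots sit mostly west of the colonies, so the west-only
colony accumulates ~30% more overlap than the colony that splits its
trips east and west — the mechanism by which spatial segregation becomes
unequal bycatch risk.

See `vignettes/colony-segregation-methods.Rmd` for the models,
conventions and numerical choices, including exactly what the synthetic
generator does and does not emulate.

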