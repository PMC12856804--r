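# Small, fast simulation configurations shared across tests.

# compact two-colony setup: short trips so grids stay small
small_config <- function(n_trips = c(4, 4, 4), birds = 5,
                         mixtures = NULL, outlier_rate = 0.01,
                         durations = c(48, 24, 36), sigma = 0.3) {
  sim_config(
    birds_per_colony = c(bird_island = birds, prion_island = birds),
    trips_per_stage = tibble::tibble(
      colony = rep(c("bird_island", "prion_island"), each = 3),
      stage = rep(c("incubation", "brood_guard", "postguard"), 2),
      n_trips = rep(n_trips, 2)),
    trip_durations = tibble::tibble(
      stage = c("incubation", "brood_guard", "postguard"),
      median_h = durations, sigma = rep(sigma, 3)),
    bearing_mixtures = if (is.null(mixtures))
      .default_small_mixtures() else mixtures,
    outlier_rate = outlier_rate
  )
}

.default_small_mixtures <- function() {
  list(
    bird_island = tibble::tibble(mean_deg = 280, kappa = 2, weight = 1),
    prion_island = tibble::tibble(mean_deg = c(290, 70), kappa = c(2, 2),
                                  weight = c(0.6, 0.4))
  )
}

# single-stage null config: both colonies draw trips from one distribution
null_config <- function(n_per_colony = 50, median_h = 18,
                        mean_deg = 180, kappa = 0.5) {
  mix <- tibble::tibble(mean_deg = mean_deg, kappa = kappa, weight = 1)
  sim_config(
    birds_per_colony = c(bird_island = n_per_colony,
                         prion_island = n_per_colony),
    trips_per_stage = tibble::tibble(
      colony = c("bird_island", "prion_island"),
      stage = "brood_guard", n_trips = n_per_colony),
    trip_durations = tibble::tibble(
      stage = c("incubation", "brood_guard", "postguard"),
      median_h = median_h, sigma = 0.3),
    bearing_mixtures = list(bird_island = mix, prion_island = mix),
    outlier_rate = 0
  )
}

# nest a simulated track table into a trip tibble using the generator's
# ground-truth trip labels (skips the splitting stage when the test's
# subject is downstream of it)
true_trips <- function(tracks) {
  tracks |>
    dplyr::filter(!is.na(trip_id)) |>
    tidyr::nest(fixes = c(timestamp, lat, lon, is_outlier)) |>
    dplyr::mutate(complete = TRUE)
}

# random UD on a small shared grid, for analytic affinity/isopleth checks
random_ud <- function(n_cells = 25, concentrate = 1) {
  grid <- structure(list(x = seq_len(5) * 10 - 5, y = seq_len(n_cells / 5) *
                           10 - 5, cell_km = 10, center = c(0, -54)),
                    class = "ud_grid_spec")
  p <- stats::rgamma(n_cells, concentrate)
  p <- p / sum(p)
  structure(list(p = matrix(p, 5, n_cells / 5), grid = grid),
            class = "ud_grid")
}
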