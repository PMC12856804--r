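one_fix <- function(lon = -38, lat = -54) tibble::tibble(lon = lon, lat = lat)

test_that("kernel UDs are unimodal, normalized and weight-invariant", {
  grid <- make_grid(one_fix(), cell_km = 10, pad_km = 200)
  ud <- kde_ud(one_fix(), grid, bw_km = 60)
  expect_equal(sum(ud$p), 1, tolerance = 1e-9)
  # argmax in the cell containing the fix
  idx <- which(ud$p == max(ud$p), arr.ind = TRUE)
  p <- project_aeqd(one_fix(), grid$center)
  expect_lt(abs(grid$x[idx[1]] - p$x), grid$cell_km)
  expect_lt(abs(grid$y[idx[2]] - p$y), grid$cell_km)

  two <- dplyr::bind_rows(one_fix(), one_fix())
  expect_equal(kde_ud(two, grid, 60)$p, ud$p, tolerance = 1e-12)
})

test_that("half the kernel mass lies within the circular-Gaussian half-mass radius", {
  bw <- 50
  grid <- make_grid(one_fix(), cell_km = 5, pad_km = 6 * bw)
  ud <- kde_ud(one_fix(), grid, bw_km = bw)
  p <- project_aeqd(one_fix(), grid$center)
  r <- sqrt(outer((grid$x - p$x)^2, (grid$y - p$y)^2, "+"))
  frac <- sum(ud$p[r <= 1.1774 * bw])
  expect_equal(frac, 0.5, tolerance = 0.02 / 0.5)
})

test_that("population UD is the renormalized mean of trip UDs", {
  grid <- make_grid(one_fix(), cell_km = 10, pad_km = 150)
  u1 <- kde_ud(one_fix(), grid, 40)
  expect_equal(population_ud(list(u1))$p, u1$p)
  expect_equal(population_ud(list(u1, u1))$p, u1$p, tolerance = 1e-12)

  # two disjoint single-cell UDs average to 0.5/0.5
  mk <- function(i) {
    p <- matrix(0, length(grid$x), length(grid$y)); p[i] <- 1
    structure(list(p = p, grid = grid), class = "ud_grid")
  }
  avg <- population_ud(list(mk(1), mk(5)))
  expect_equal(sort(avg$p[avg$p > 0]), c(0.5, 0.5))
})

test_that("isopleths are the minimal top-density sets", {
  grid <- structure(list(x = c(5, 15), y = c(5, 15), cell_km = 10,
                         center = c(0, -54)), class = "ud_grid_spec")
  unif <- structure(list(p = matrix(0.25, 2, 2), grid = grid),
                    class = "ud_grid")
  expect_equal(sum(isopleth(unif, 0.5)$mask), 2)
  point <- structure(list(p = matrix(c(1, 0, 0, 0), 2, 2), grid = grid),
                     class = "ud_grid")
  expect_equal(sum(isopleth(point, 0.95)$mask), 1)

  set.seed(99)
  for (i in 1:50) {
    ud <- random_ud()
    lev <- runif(1, 0.2, 0.9)
    iso <- isopleth(ud, lev)
    expect_gte(iso$contained, lev)
    expect_lte(iso$contained, lev + max(ud$p))
    # minimality: dropping the smallest selected cell goes below the level
    expect_lt(iso$contained - min(ud$p[iso$mask]), lev)
  }
})

test_that("Bhattacharyya affinity matches analytic values and symmetries", {
  ud <- random_ud()
  expect_equal(bhattacharyya(ud, ud), 1, tolerance = 1e-9)

  grid <- ud$grid
  mk <- function(p) structure(list(p = matrix(p, 5, 5), grid = grid),
                              class = "ud_grid")
  a <- c(0.5, 0.5, rep(0, 23)); b <- c(0.25, 0.75, rep(0, 23))
  expect_equal(bhattacharyya(mk(a), mk(b)),
               sqrt(0.5 * 0.25) + sqrt(0.5 * 0.75), tolerance = 1e-9)
  disj <- c(rep(0, 23), 0.4, 0.6)
  expect_equal(bhattacharyya(mk(a), mk(disj)), 0)

  set.seed(123)
  for (i in 1:25) {
    u <- random_ud(); v <- random_ud()
    ba <- bhattacharyya(u, v)
    expect_gte(ba, 0); expect_lte(ba, 1 + 1e-12)
    expect_equal(ba, bhattacharyya(v, u))
    perm <- sample(25)
    expect_equal(bhattacharyya(mk(as.numeric(u$p)[perm]),
                               mk(as.numeric(v$p)[perm])), ba)
  }
})

test_that("segregation test is internally consistent and seeded", {
  cfg <- null_config(n_per_colony = 6, median_h = 15)
  trips <- true_trips(simulate_tracks(cfg, seed = 3))
  a <- trips[trips$colony == "bird_island", ]
  b <- trips[trips$colony == "prion_island", ]
  grid <- make_grid(dplyr::bind_rows(trips$fixes), cell_km = 25,
                    pad_km = 3 * 60)
  res <- suppressWarnings(
    segregation_test(a, b, bw_km = 60, cell_km = 25, n_iter = 50, seed = 2,
                     grid = grid))
  ud_a <- population_ud(purrr::map(a$fixes, kde_ud, grid = grid, bw_km = 60))
  ud_b <- population_ud(purrr::map(b$fixes, kde_ud, grid = grid, bw_km = 60))
  expect_equal(res$observed_ba, bhattacharyya(ud_a, ud_b), tolerance = 1e-9)
  # p-value is the plain proportion of smaller null affinities
  expect_equal(res$p_value, sum(res$null_ba < res$observed_ba) / res$n_iter)
  res2 <- suppressWarnings(
    segregation_test(a, b, bw_km = 60, cell_km = 25, n_iter = 50, seed = 2,
                     grid = grid))
  expect_identical(res$null_ba, res2$null_ba)
  expect_warning(
    segregation_test(a, b, bw_km = 60, cell_km = 25, n_iter = 50, seed = 1,
                     grid = grid), "unstable")
  # the +1 variant never returns exactly zero
  res3 <- suppressWarnings(
    segregation_test(a, b, bw_km = 60, cell_km = 25, n_iter = 50, seed = 2,
                     grid = grid, plus_one = TRUE))
  expect_gt(res3$p_value, 0)
})

test_that("isopleth-restricted affinity is bounded and 1 for identical UDs", {
  set.seed(5)
  u <- random_ud(); v <- random_ud()
  expect_equal(bhattacharyya_isopleth(u, u, 0.5), 1, tolerance = 1e-9)
  ba <- bhattacharyya_isopleth(u, v, 0.5)
  expect_gte(ba, 0); expect_lte(ba, 1 + 1e-12)
})

test_that("representativeness saturates for exchangeable trips", {
  # 8 identical trips: any subset's core contains the others' fixes
  fx <- destination_point(-38, -54, seq(10, 350, by = 30), 80)
  fx <- tibble::tibble(lon = fx$lon, lat = fx$lat)
  trips <- tibble::tibble(
    trip_id = sprintf("t%d", 1:8), bird_id = sprintf("b%d", 1:8),
    colony = "bird_island", complete = TRUE,
    fixes = purrr::map(1:8, function(i) fx))
  r <- representativeness(trips, bw_km = 60, cell_km = 20, n_boot = 5,
                          seed = 1)
  expect_gt(r$percent, 99)

  # N = 2 is defined but flagged
  expect_warning(r2 <- representativeness(trips[1:2, ], bw_km = 60,
                                          cell_km = 20, n_boot = 3,
                                          seed = 1),
                 "Too few")
  expect_true(r2$low_confidence)
  expect_true(is.finite(r2$percent))
})

test_that("per-bird core areas respect counting identities", {
  cfg <- null_config(n_per_colony = 6, median_h = 15)
  trips <- true_trips(simulate_tracks(cfg, seed = 11)) |>
    dplyr::filter(colony == "bird_island")
  ca <- individual_core_areas(trips, bw_km = 60, cell_km = 25)
  # one bird, one trip: equals that trip's own core
  one <- individual_core_areas(trips[1, ], bw_km = 60, cell_km = 25,
                               grid = ca$grid)
  trip_ud <- kde_ud(trips$fixes[[1]], ca$grid, 60)
  expect_equal(one$per_bird$core[[1]]$mask, isopleth(trip_ud, 0.5)$mask)
  # cell-wise bird counts sum to the sum of core sizes
  expect_equal(sum(ca$bird_count), sum(ca$per_bird$n_core_cells))
  expect_lte(max(ca$bird_count), nrow(ca$per_bird))
})

test_that("UD tidying and GeoJSON export cover the whole grid", {
  grid <- make_grid(one_fix(), cell_km = 20, pad_km = 100)
  ud <- kde_ud(one_fix(), grid, 50)
  td <- tidy(ud)
  expect_equal(nrow(td), length(grid$x) * length(grid$y))
  expect_equal(sum(td$p), 1, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_isopleth_geojson(ud, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
})
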