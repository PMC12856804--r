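make_fixes <- function(lon, lat, hours, bird = "b1", colony = "bird_island") {
  tibble::tibble(
    bird_id = bird, colony = colony,
    timestamp = as.POSIXct("2022-02-01", tz = "UTC") + hours * 3600,
    lat = lat, lon = lon)
}

test_that("speed filter keeps stationary tracks and removes single outliers", {
  still <- make_fixes(rep(-38, 5), rep(-54, 5), 0:4)
  kept <- speed_filter(still)
  expect_equal(nrow(kept), 5)
  expect_equal(nrow(attr(kept, "removed")), 0)

  # a fix displaced 150 km between neighbours one hour apart
  path <- destination_point(-38, -54, 90, seq(0, 80, by = 20))
  track <- make_fixes(path$lon, path$lat, 0:4)
  out <- destination_point(track$lon[3], track$lat[3], 0, 150)
  track$lon[3] <- out$lon; track$lat[3] <- out$lat
  kept <- speed_filter(track)
  expect_equal(nrow(kept), 4)
  expect_equal(attr(kept, "removed")$timestamp, track$timestamp[3])
})

test_that("speed filter removes exactly the injected synthetic outliers", {
  cfg <- small_config(outlier_rate = 0.03)
  tr <- simulate_tracks(cfg, seed = 21)
  expect_gt(sum(tr$is_outlier), 0)
  kept <- speed_filter(tr)
  removed <- attr(kept, "removed")
  expect_equal(nrow(removed), sum(tr$is_outlier))
  expect_true(all(removed$is_outlier))
})

test_that("speed filter rejects duplicate timestamps with the bird id", {
  dup <- make_fixes(c(-38, -38, -38), c(-54, -54, -54), c(0, 1, 1))
  expect_error(speed_filter(dup), "b1")
})

test_that("filtered output never implies speeds above the ceiling", {
  cfg <- small_config(outlier_rate = 0.05)
  kept <- speed_filter(simulate_tracks(cfg, seed = 8), vmax_kmh = 80)
  bad <- kept |>
    dplyr::group_by(bird_id) |>
    dplyr::summarise(n_bad = {
      n <- dplyr::n()
      d <- great_circle_km(lon[-n], lat[-n], lon[-1], lat[-1])
      dt <- as.numeric(diff(timestamp), units = "hours")
      sum(d / dt > 80)
    })
  expect_equal(sum(bad$n_bad), 0)
})

test_that("regularize is the identity on already-hourly tracks", {
  path <- destination_point(-38, -54, 270, seq(0, 100, by = 25))
  track <- make_fixes(path$lon, path$lat, 0:4)
  reg <- regularize(track)
  expect_equal(reg$lat, track$lat)
  expect_equal(reg$lon, track$lon)
  expect_equal(reg$timestamp, track$timestamp)
})

test_that("regularize interpolates midpoints and respects the gap limit", {
  two <- make_fixes(c(-38, -38), c(-54, -53), c(0, 2))
  reg <- regularize(two)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$lat[2], -53.5)
  expect_equal(reg$lon[2], -38)

  gap <- make_fixes(c(-38, -38, -38, -38), c(-54, -53.9, -50, -49.9),
                    c(0, 1, 40, 41))
  reg <- regularize(gap, max_gap_h = 12)
  # no marks inside the 39-hour hole
  expect_equal(nrow(reg), 4)
})

test_that("hourly marks on a dense 5-minute track sit near raw fixes", {
  cfg <- small_config(n_trips = c(0, 2, 0), outlier_rate = 0,
                      durations = c(24, 24, 24))
  cfg$fix_interval_h <- 5 / 60
  tr <- simulate_tracks(cfg, seed = 13)
  reg <- regularize(tr)
  expect_gt(nrow(reg), 10)
  near <- vapply(seq_len(nrow(reg)), function(i) {
    b <- tr[tr$bird_id == reg$bird_id[i], ]
    min(great_circle_km(reg$lon[i], reg$lat[i], b$lon, b$lat))
  }, numeric(1))
  expect_lt(max(near), 1)
})

test_that("trip splitting handles hand-built excursion patterns", {
  col <- default_colonies()[1, ]
  # never leaves the buffer: no trips
  loaf <- make_fixes(rep(col$lon, 30), rep(col$lat, 30), 0:29)
  expect_equal(nrow(split_trips(loaf, col)), 0)

  # out 10 h and back, then out 5 h with no return
  away <- destination_point(col$lon, col$lat, 270, 60)
  mk <- function(h, at) {
    if (at) make_fixes(col$lon, col$lat, h) else
      make_fixes(away$lon, away$lat, h)
  }
  track <- dplyr::bind_rows(
    mk(0, TRUE), purrr::map_dfr(1:9, mk, at = FALSE), mk(10, TRUE),
    mk(11, TRUE), purrr::map_dfr(12:16, mk, at = FALSE))
  trips <- split_trips(track, col, min_trip_h = 3)
  expect_equal(nrow(trips), 2)
  expect_equal(trips$complete, c(TRUE, FALSE))
  # complete trip runs from last inside fix to first inside fix back
  expect_equal(trips$start[1], track$timestamp[1])
  expect_equal(trips$end[1], track$timestamp[11])

  # warning when no fix is ever at the colony
  far <- make_fixes(rep(away$lon, 4), rep(away$lat, 4), 0:3)
  expect_warning(split_trips(far, col), "buffer")
})

test_that("trip splitting recovers the generated trip count", {
  cfg <- small_config(outlier_rate = 0)
  tr <- simulate_tracks(cfg, seed = 31)
  reg <- regularize(tr)
  cols <- default_colonies()
  for (cn in cols$colony) {
    trips <- split_trips(dplyr::filter(reg, colony == cn),
                         cols[cols$colony == cn, ])
    truth <- dplyr::n_distinct(tr$trip_id[tr$colony == cn &
                                            !is.na(tr$trip_id)])
    expect_equal(nrow(trips), truth)
    expect_true(all(trips$complete))
  }
})

test_that("away-from-colony fixes belong to exactly one trip", {
  cfg <- small_config(outlier_rate = 0)
  tr <- simulate_tracks(cfg, seed = 31)
  reg <- regularize(tr)
  col <- default_colonies()[1, ]
  trips <- split_trips(dplyr::filter(reg, colony == "bird_island"), col)
  claimed <- purrr::map_dfr(trips$fixes, function(f) {
    d <- great_circle_km(col$lon, col$lat, f$lon, f$lat)
    f[d > col$buffer_km, c("timestamp", "lat", "lon")]
  })
  bi <- dplyr::filter(reg, colony == "bird_island")
  outside <- bi[great_circle_km(col$lon, col$lat, bi$lon, bi$lat) >
                  col$buffer_km, ]
  expect_equal(nrow(claimed), nrow(outside))
  expect_equal(anyDuplicated(claimed), 0)
})

test_that("stage assignment follows windows then the attendance rule", {
  col <- default_colonies()[1, ]
  mk_trip <- function(start_day, dur_h, next_gap_h = NA) {
    start <- as.POSIXct(start_day, tz = "UTC")
    tibble::tibble(
      trip_id = paste0("t", start_day), bird_id = "b1",
      colony = col$colony, complete = TRUE,
      start = start, end = start + dur_h * 3600, n_fixes = 10L,
      fixes = list(tibble::tibble()))
  }
  # wholly in February: incubation
  feb <- mk_trip("2022-02-01", 100)
  expect_equal(infer_stage(feb)$stage, "incubation")
  # wholly in June: postguard (unique window)
  jun <- mk_trip("2022-06-10", 100)
  expect_equal(infer_stage(jun)$stage, "postguard")

  # ends 10 April (brood/postguard overlap); 20 h attendance before the
  # next trip points to the earlier stage
  overlap_trip <- mk_trip("2022-04-07", 72)           # ends 10 Apr
  follow <- mk_trip("2022-04-28", 24)
  follow$start <- overlap_trip$end + 20 * 3600        # 20 h at the nest
  follow$end <- follow$start + 24 * 3600
  both <- infer_stage(dplyr::bind_rows(overlap_trip, follow))
  expect_equal(both$stage[1], "brood_guard")

  # only 6 h attendance: the later stage
  follow$start <- overlap_trip$end + 6 * 3600
  follow$end <- follow$start + 24 * 3600
  both <- infer_stage(dplyr::bind_rows(overlap_trip, follow))
  expect_equal(both$stage[1], "postguard")
})

test_that("trip metrics match a hand-built out-and-back trip", {
  col <- default_colonies()[1, ]
  west <- destination_point(col$lon, col$lat, 270, 30)
  fixes <- dplyr::bind_rows(
    make_fixes(col$lon, col$lat, 0),
    make_fixes(west$lon, west$lat, 1),
    make_fixes(col$lon, col$lat, 2))
  trip <- tibble::tibble(trip_id = "t1", bird_id = "b1", colony = col$colony,
                         complete = TRUE, start = fixes$timestamp[1],
                         end = fixes$timestamp[3], n_fixes = 3L,
                         fixes = list(fixes))
  m <- trip_metrics(trip, col)
  expect_equal(m$duration_h, 2)
  expect_equal(m$total_distance_km, 60, tolerance = 1e-6)
  expect_equal(m$foraging_range_km, 30, tolerance = 1e-6)
  expect_equal(m$bearing_far_deg, 270, tolerance = 0.01)

  # degenerate: one off-colony fix
  single <- trip
  single$fixes <- list(fixes[1:2, ])
  expect_equal(trip_metrics(single, col)$foraging_range_km, 30,
               tolerance = 1e-6)
})

test_that("total distance is invariant to collinear midpoint insertion", {
  col <- default_colonies()[1, ]
  pts <- project_aeqd(destination_point(col$lon, col$lat, 250,
                                        c(0, 100, 200)),
                      c(col$lon, col$lat))
  dense_xy <- tibble::tibble(x = seq(0, pts$x[3], length.out = 9),
                             y = seq(0, pts$y[3], length.out = 9))
  dense <- unproject_aeqd(dense_xy$x, dense_xy$y, c(col$lon, col$lat))
  mk <- function(ll, hrs) tibble::tibble(
    trip_id = "t", bird_id = "b", colony = col$colony, complete = TRUE,
    start = as.POSIXct("2022-02-01", tz = "UTC"),
    end = as.POSIXct("2022-02-01", tz = "UTC") + max(hrs) * 3600,
    n_fixes = nrow(ll),
    fixes = list(make_fixes(ll$lon, ll$lat, hrs)))
  coarse <- trip_metrics(mk(dense[c(1, 5, 9), ], c(0, 4, 8)), col)
  fine <- trip_metrics(mk(dense, 0:8), col)
  expect_equal(fine$total_distance_km, coarse$total_distance_km,
               tolerance = 1e-4)
})

test_that("summaries use complete trips only and track generator targets", {
  cfg <- small_config(outlier_rate = 0)
  tr <- simulate_tracks(cfg, seed = 17)
  reg <- regularize(tr)
  cols <- default_colonies()
  col <- cols[1, ]
  trips <- infer_stage(split_trips(dplyr::filter(reg, colony ==
                                                   "bird_island"), col))
  m <- trip_metrics(trips, col)
  m2 <- m
  m2$complete[1] <- FALSE
  s_all <- trip_summary(m)
  s_drop <- trip_summary(m2)
  expect_equal(sum(s_all$n_trips) - 1, sum(s_drop$n_trips))

  # duration magnitudes follow the configured log-normals
  med <- cfg$trip_durations
  for (st in unique(m$stage)) {
    target <- med$median_h[med$stage == st]
    got <- median(m$duration_h[m$stage == st])
    expect_lt(abs(got - target) / target, 0.6)
  }
})

test_that("track CSV round-trips through the five-column schema", {
  cfg <- small_config(n_trips = c(1, 0, 0))
  tr <- simulate_tracks(cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tr, path)
  back <- read_tracks_csv(path)
  expect_named(back, c("bird_id", "colony", "timestamp", "lat", "lon"))
  expect_equal(back$timestamp, tr$timestamp)
  expect_equal(back$lat, tr$lat, tolerance = 1e-6)
})
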