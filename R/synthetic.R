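# Seeded synthetic two-colony tracking, wind, effort and covariate data.
# The generator emulates the statistical structure the downstream analysis
# assumes: central-place trips with outbound/forage/return phases, colony-
# specific departure-bearing mixtures, predominantly southwesterly winds,
# and spatially clustered fishing effort.

#' Default breeding-stage calendar windows
#'
#' Half-open UTC windows `[start, end)` for incubation, brood guard and
#' postguard. Incubation and brood guard overlap in March, and brood guard
#' and postguard overlap in April, so stage inference from colony attendance
#' is genuinely exercised.
#'
#' @param year Calendar year the season starts in.
#' @return Tibble with columns `stage`, `start`, `end` (POSIXct, UTC).
#' @export
stage_windows <- function(year = 2022) {
  ts <- function(d) as.POSIXct(paste0(year, "-", d), tz = "UTC")
  tibble::tibble(
    stage = c("incubation", "brood_guard", "postguard"),
    start = ts(c("01-09", "03-02", "04-05")),
    end   = ts(c("03-30", "04-19", "08-19"))
  )
}

#' Default colony table
#'
#' Two wandering-albatross colonies in the South Georgia archipelago,
#' roughly 42 km apart: far closer together than the foraging ranges of the
#' birds breeding there.
#'
#' @param buffer_km Radius (km) within which a fix counts as "at the colony".
#' @return Tibble with columns `colony`, `lat`, `lon`, `buffer_km`.
#' @export
default_colonies <- function(buffer_km = 5) {
  tibble::tibble(
    colony = c("bird_island", "prion_island"),
    lat = c(-54.000, -54.0333),
    lon = c(-38.050, -37.4167),
    buffer_km = buffer_km
  )
}

.default_bearing_mixtures <- function() {
  list(
    # bird_island birds head almost exclusively west
    bird_island = tibble::tibble(mean_deg = 280, kappa = 2, weight = 1),
    # prion_island birds split between westerly and easterly destinations
    prion_island = tibble::tibble(mean_deg = c(290, 70), kappa = c(2, 2),
                                  weight = c(0.6, 0.4))
  )
}

.default_trip_durations <- function() {
  tibble::tibble(
    stage = c("incubation", "brood_guard", "postguard"),
    median_h = c(300, 75, 160),
    sigma = c(0.35, 0.40, 0.60)
  )
}

# colony attendance after a trip: long sits while an egg or small chick is
# attended, brief feeding visits once the chick is left alone
.default_attendance <- function() {
  tibble::tibble(
    stage = c("incubation", "brood_guard", "postguard"),
    median_h = c(30, 24, 8),
    sigma = c(0.4, 0.4, 0.5)
  )
}

.default_trips_per_stage <- function() {
  tibble::tibble(
    colony = rep(c("bird_island", "prion_island"), each = 3),
    stage = rep(c("incubation", "brood_guard", "postguard"), 2),
    n_trips = c(17, 26, 34, 25, 44, 118)
  )
}

.default_hotspots <- function() {
  spots <- tibble::tibble(
    lat = c(-52, -45, -54.5, -47, -51, -53),
    lon = c(-60, -58, -40, -52, -61, -35),
    radius_km = c(300, 350, 200, 300, 250, 250),
    flag = c("ARG", "CHN", "KOR", "TWN", "CHN", "KOR"),
    gear = c("trawler", "squid_jigger", "set_longline",
             "drifting_longline", "squid_jigger", "set_longline"),
    rel_hours = c(5000, 6000, 2500, 600, 4000, 1500)
  )
  # effort present in every stage, scaled by window length
  scale <- c(incubation = 1, brood_guard = 0.6, postguard = 1.7)
  purrr::map_dfr(names(scale), function(st) {
    dplyr::mutate(spots, stage = st, hours = rel_hours * scale[[st]])
  }) |> dplyr::select(-rel_hours)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults sized to
#' the two-colony study system the package is built around: hourly fixes,
#' trips lasting tens to hundreds of hours with foraging ranges of hundreds
#' to ~2000 km, westerly-dominated departure bearings at one colony and an
#' east/west mixture at the other, southwesterly winds, and clustered
#' fishing effort by gear and flag.
#'
#' @param colonies Colony tibble, see [default_colonies()].
#' @param birds_per_colony Named integer vector of birds per colony.
#' @param trips_per_stage Tibble `colony`, `stage`, `n_trips`.
#' @param windows Stage calendar, see [stage_windows()].
#' @param fix_interval_h Fix interval, hours.
#' @param bearing_mixtures Named list (per colony) of tibbles
#'   `mean_deg`, `kappa`, `weight` describing a von Mises mixture of
#'   departure bearings. Weights must sum to 1.
#' @param speed_kmh,speed_sd_kmh Mean and SD of outbound ground speed, km/h.
#' @param trip_durations Tibble `stage`, `median_h`, `sigma` of the
#'   log-normal trip-duration distribution per stage.
#' @param attendance Tibble `stage`, `median_h`, `sigma` of the log-normal
#'   post-trip colony-attendance distribution (long during incubation and
#'   brood guard, short feeding visits during postguard).
#' @param outlier_rate Probability that an interior fix is displaced to form
#'   an implausible-speed outlier.
#' @param outlier_km Displacement distance for injected outliers, km.
#' @param speed_ceiling_kmh Speed ceiling that non-outlier fixes respect.
#' @param wind List: `from_mean_deg`, `kappa`, `speed_mean_ms`, `speed_sd_ms`.
#' @param hotspots Effort hotspot tibble `lat`, `lon`, `radius_km`, `flag`,
#'   `gear`, `stage`, `hours`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(colonies = default_colonies(),
                       birds_per_colony = c(bird_island = 30, prion_island = 10),
                       trips_per_stage = .default_trips_per_stage(),
                       windows = stage_windows(),
                       fix_interval_h = 1,
                       bearing_mixtures = .default_bearing_mixtures(),
                       speed_kmh = 25, speed_sd_kmh = 7,
                       trip_durations = .default_trip_durations(),
                       attendance = .default_attendance(),
                       outlier_rate = 0.01, outlier_km = 250,
                       speed_ceiling_kmh = 80,
                       wind = list(from_mean_deg = 225, kappa = 1.5,
                                   speed_mean_ms = 9, speed_sd_ms = 3),
                       hotspots = .default_hotspots()) {
  if (any(!is.finite(colonies$lat)) || any(!is.finite(colonies$lon))) {
    rlang::abort("Non-finite colony coordinates.")
  }
  for (nm in names(bearing_mixtures)) {
    w <- bearing_mixtures[[nm]]$weight
    if (abs(sum(w) - 1) > 1e-8) {
      rlang::abort(paste0("Bearing-mixture weights for ", nm,
                          " must sum to 1."))
    }
    if (any(bearing_mixtures[[nm]]$kappa < 0)) {
      rlang::abort("Negative von Mises concentration.")
    }
  }
  stopifnot(speed_sd_kmh >= 0, outlier_rate >= 0, outlier_rate <= 1,
            fix_interval_h > 0, speed_ceiling_kmh > 0,
            all(windows$end > windows$start))
  structure(list(
    colonies = colonies, birds_per_colony = birds_per_colony,
    trips_per_stage = trips_per_stage, windows = windows,
    fix_interval_h = fix_interval_h, bearing_mixtures = bearing_mixtures,
    speed_kmh = speed_kmh, speed_sd_kmh = speed_sd_kmh,
    trip_durations = trip_durations, attendance = attendance,
    outlier_rate = outlier_rate,
    outlier_km = outlier_km, speed_ceiling_kmh = speed_ceiling_kmh,
    wind = wind, hotspots = hotspots
  ), class = "sim_config")
}

# one trip as planar steps (km east/north of colony), first and last at (0,0)
.sim_trip_xy <- function(n_steps, bearing_deg, cfg) {
  dt <- cfg$fix_interval_h
  cap <- 0.9 * cfg$speed_ceiling_kmh * dt
  n_out <- max(1L, ceiling(0.4 * n_steps))
  n_for <- max(1L, ceiling(0.2 * n_steps))
  n_ret <- max(1L, n_steps - n_out - n_for)

  draw_speed <- function(m, mult = 1) {
    s <- stats::rnorm(m, cfg$speed_kmh * mult, cfg$speed_sd_kmh * mult)
    pmin(pmax(s, 2), cap / dt)
  }
  # outbound: tight correlated headings around the departure bearing
  h_out <- rvonmises(n_out, bearing_deg, 8)
  s_out <- draw_speed(n_out)
  # foraging: slow, tortuous
  h_for <- rvonmises(n_for, bearing_deg, 0.3)
  s_for <- draw_speed(n_for, 0.35)
  h <- deg2rad(c(h_out, h_for))
  s <- c(s_out, s_for)
  x <- cumsum(s * dt * sin(h))
  y <- cumsum(s * dt * cos(h))
  # homing: shrink the remaining distance to zero with bearing jitter,
  # extending the trip if the straight-line return would break the ceiling
  px <- x[length(x)]; py <- y[length(y)]
  rx <- ry <- numeric(0)
  m <- n_ret
  while (sqrt(px^2 + py^2) / m > 0.8 * cap) m <- m + 1L
  for (i in seq_len(m)) {
    d <- sqrt(px^2 + py^2)
    left <- m - i + 1L
    if (i == m || d < 1e-9) {
      px <- 0; py <- 0
    } else {
      step <- min(d / left, cap)
      th <- atan2(-px, -py) + deg2rad(stats::rnorm(1, 0, 10))
      px <- px + step * sin(th)
      py <- py + step * cos(th)
    }
    rx <- c(rx, px); ry <- c(ry, py)
  }
  tibble::tibble(x = c(0, x, rx), y = c(0, y, ry))
}

#' Simulate a seeded set of central-place foraging trips
#'
#' Generates one row per hourly fix for every configured trip, plus hourly
#' colony-attendance fixes between consecutive trips of the same bird. Trips
#' start and end exactly at the colony; each departs along a bearing drawn
#' from the colony's von Mises mixture, travels out with correlated
#' random-walk legs, forages (slower, more tortuous), then homes. A known
#' fraction of interior fixes is displaced to create implausible-speed
#' outliers, flagged in `is_outlier` so filtering can be checked against
#' ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is deterministic given `(config, seed)`.
#' @return Tibble with columns `bird_id`, `colony`, `trip_id`, `stage_true`,
#'   `timestamp`, `lat`, `lon`, `is_outlier`, `bearing_true`. Attendance
#'   fixes have `trip_id = NA`.
#' @export
simulate_tracks <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cfg <- config
  rows <- list()
  stage_order <- cfg$windows$stage
  for (ci in seq_len(nrow(cfg$colonies))) {
    col <- cfg$colonies[ci, ]
    nb <- cfg$birds_per_colony[[col$colony]]
    if (is.null(nb) || nb < 1) next
    center <- c(col$lon, col$lat)
    # assign trips to birds round-robin within each stage
    plan <- cfg$trips_per_stage |>
      dplyr::filter(.data$colony == col$colony, .data$n_trips > 0) |>
      dplyr::mutate(stage = factor(.data$stage, levels = stage_order)) |>
      dplyr::arrange(.data$stage)
    if (nrow(plan) == 0) next
    assignments <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
      tibble::tibble(stage = as.character(plan$stage[i]),
                     bird = (seq_len(plan$n_trips[i]) - 1L) %% nb + 1L)
    })
    clock <- rep(as.POSIXct(NA, tz = "UTC"), nb)
    trip_no <- 0L
    for (i in seq_len(nrow(assignments))) {
      st <- assignments$stage[i]
      b <- assignments$bird[i]
      w <- cfg$windows[cfg$windows$stage == st, ]
      dur <- cfg$trip_durations[cfg$trip_durations$stage == st, ]
      D <- stats::rlnorm(1, log(dur$median_h), dur$sigma)
      n_steps <- max(4L, as.integer(round(D / cfg$fix_interval_h)))
      # departure time: a whole-hour mark within the stage window (fixes
      # live on the hourly lattice, like interpolated tracking data),
      # after the bird's clock
      off_h <- floor(stats::runif(1, 0, 0.8) *
                       as.numeric(difftime(w$end, w$start, units = "hours")))
      t0 <- w$start + off_h * 3600
      if (!is.na(clock[b]) && clock[b] >= t0) t0 <- clock[b]
      mix <- cfg$bearing_mixtures[[col$colony]]
      comp <- sample.int(nrow(mix), 1, prob = mix$weight)
      bearing <- rvonmises(1, mix$mean_deg[comp], mix$kappa[comp])
      xy <- .sim_trip_xy(n_steps, bearing, cfg)
      ll <- unproject_aeqd(xy$x, xy$y, center)
      n_fix <- nrow(xy)
      times <- t0 + (seq_len(n_fix) - 1) * 3600 * cfg$fix_interval_h
      is_out <- rep(FALSE, n_fix)
      interior <- 2:(n_fix - 1)
      hit <- interior[stats::runif(length(interior)) < cfg$outlier_rate]
      if (length(hit) > 0) {
        th <- stats::runif(length(hit), 0, 360)
        disp <- destination_point(ll$lon[hit], ll$lat[hit], th, cfg$outlier_km)
        ll$lon[hit] <- disp$lon; ll$lat[hit] <- disp$lat
        is_out[hit] <- TRUE
      }
      trip_no <- trip_no + 1L
      bird_id <- sprintf("%s_b%02d", col$colony, b)
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = bird_id, colony = col$colony,
        trip_id = sprintf("%s_t%03d", col$colony, trip_no),
        stage_true = st, timestamp = times,
        lat = ll$lat, lon = ll$lon, is_outlier = is_out,
        bearing_true = bearing
      )
      # colony attendance until the clock releases the bird again
      att <- cfg$attendance[cfg$attendance$stage == st, ]
      gap_h <- stats::rlnorm(1, log(att$median_h), att$sigma)
      n_att <- max(1L, as.integer(floor(gap_h / cfg$fix_interval_h)))
      att_times <- times[n_fix] + seq_len(n_att) * 3600 * cfg$fix_interval_h
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = bird_id, colony = col$colony, trip_id = NA_character_,
        stage_true = NA_character_, timestamp = att_times,
        lat = col$lat, lon = col$lon, is_outlier = FALSE,
        bearing_true = NA_real_
      )
      clock[b] <- att_times[n_att] + 3600 * cfg$fix_interval_h
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      bird_id = character(), colony = character(), trip_id = character(),
      stage_true = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      lat = numeric(), lon = numeric(), is_outlier = logical(),
      bearing_true = numeric()
    ))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$colony, .data$bird_id, .data$timestamp)
}

#' Simulate wind at departure
#'
#' One wind vector per departure, with the "from" direction drawn from a von
#' Mises distribution and speed from a (non-negative truncated) Gaussian.
#'
#' @param departures Tibble with at least `trip_id` and `timestamp`.
#' @param config A [sim_config()]; uses its `wind` block.
#' @param seed Integer seed.
#' @return Tibble `trip_id`, `timestamp`, `u_ms`, `v_ms`, `speed_ms`,
#'   `from_direction`.
#' @export
simulate_wind <- function(departures, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"), nrow(departures) > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- config$wind
  n <- nrow(departures)
  from <- rvonmises(n, w$from_mean_deg, w$kappa)
  speed <- pmax(0, stats::rnorm(n, w$speed_mean_ms, w$speed_sd_ms))
  uv <- wind_to_uv(speed, from)
  tibble::tibble(
    trip_id = departures$trip_id, timestamp = departures$timestamp,
    u_ms = uv$u, v_ms = uv$v, speed_ms = speed, from_direction = from
  )
}

#' Simulate a gridded fishing-effort table
#'
#' Deposits each hotspot's hour budget over the 1-degree cells whose centres
#' lie within its radius, with Gaussian decay by distance from the hotspot
#' centre (scale = radius/2). Budgets are conserved exactly: allocation is
#' proportional to the truncated Gaussian weights. A hotspot smaller than
#' one cell puts all its hours in the containing cell.
#'
#' @param config A [sim_config()]; uses its `hotspots` block.
#' @param seed Accepted for interface symmetry; deposition is deterministic.
#' @return Effort tibble `lat_center`, `lon_center`, `flag`, `gear`,
#'   `stage`, `hours`.
#' @export
simulate_effort <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  hs <- config$hotspots
  if (is.null(hs) || nrow(hs) == 0) {
    return(tibble::tibble(lat_center = numeric(), lon_center = numeric(),
                          flag = character(), gear = character(),
                          stage = character(), hours = numeric()))
  }
  out <- purrr::map_dfr(seq_len(nrow(hs)), function(i) {
    h <- hs[i, ]
    ncell <- ceiling(h$radius_km / 111) + 1
    lat0 <- floor(h$lat); lon0 <- floor(h$lon)
    cells <- tidyr::expand_grid(
      lat_center = (lat0 - ncell):(lat0 + ncell) + 0.5,
      lon_center = (lon0 - ncell):(lon0 + ncell) + 0.5
    )
    d <- great_circle_km(h$lon, h$lat, cells$lon_center, cells$lat_center)
    keep <- d <= h$radius_km
    if (!any(keep)) {
      cells <- tibble::tibble(lat_center = lat0 + 0.5,
                              lon_center = lon0 + 0.5)
      wgt <- 1
    } else {
      cells <- cells[keep, ]
      wgt <- exp(-d[keep]^2 / (2 * (h$radius_km / 2)^2))
    }
    dplyr::mutate(cells, flag = h$flag, gear = h$gear, stage = h$stage,
                  hours = h$hours * wgt / sum(wgt))
  })
  out |>
    dplyr::group_by(.data$lat_center, .data$lon_center, .data$flag,
                    .data$gear, .data$stage) |>
    dplyr::summarise(hours = sum(.data$hours), .groups = "drop")
}

#' Simulate smooth gridded environmental covariates
#'
#' Gaussian random fields built by separable Gaussian smoothing of white
#' noise, rescaled to a target mean and SD; fields flagged `positive` are
#' exponentiated (log-normal surface) so log/sqrt transforms downstream are
#' well defined.
#'
#' @param grid List with `lat` and `lon` numeric vectors of cell centres.
#' @param fields Tibble `name`, `mean`, `sd`, `smoothness_cells`, `positive`.
#' @param seed Integer seed.
#' @return Long tibble `lat`, `lon`, `name`, `value`.
#' @export
simulate_covariates <- function(grid,
                                fields = tibble::tibble(
                                  name = c("depth", "sst", "sst_sd", "eke",
                                           "chla"),
                                  mean = c(3000, 5, 1, 0.02, 0.5),
                                  sd = c(1500, 4, 0.4, 0.03, 0.4),
                                  smoothness_cells = c(4, 6, 3, 2, 3),
                                  positive = c(TRUE, FALSE, TRUE, TRUE, TRUE)
                                ),
                                seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  smooth_field <- function(sm) {
    z <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
    if (sm > 0) {
      k <- stats::dnorm(seq(-ceiling(3 * sm), ceiling(3 * sm)), sd = sm)
      k <- k / sum(k)
      L <- length(k)
      conv1 <- function(v) {
        vp <- c(rev(v[seq_len(min(L, length(v)))]),
                v,
                rev(v)[seq_len(min(L, length(v)))])
        # fall back to wrap-around padding when the kernel outsizes the axis
        while (length(vp) < length(v) + 2 * L) vp <- c(vp, rev(vp))
        vp <- vp[seq_len(length(v) + 2 * L)]
        as.numeric(stats::filter(vp, k, sides = 2))[L + seq_along(v)]
      }
      z <- apply(z, 2, conv1)
      z <- t(apply(t(z), 2, conv1))
      z <- matrix(as.numeric(z), nlat, nlon)
    }
    s <- stats::sd(z)
    if (s < 1e-12) matrix(0, nlat, nlon) else (z - mean(z)) / s
  }
  purrr::map_dfr(seq_len(nrow(fields)), function(i) {
    f <- fields[i, ]
    z <- smooth_field(f$smoothness_cells)
    if (isTRUE(f$positive) && f$sd > 0 && f$mean > 0) {
      # log-normal with the requested mean/sd on the natural scale
      cv2 <- (f$sd / f$mean)^2
      slog <- sqrt(log(1 + cv2))
      mlog <- log(f$mean) - slog^2 / 2
      val <- exp(mlog + slog * z)
    } else if (isTRUE(f$positive)) {
      val <- exp(f$mean + f$sd * z)
    } else {
      val <- f$mean + f$sd * z
    }
    # expand_grid(lat, lon) varies lon fastest: row-major over the matrix
    tidyr::expand_grid(lat = grid$lat, lon = grid$lon) |>
      dplyr::mutate(name = f$name, value = as.numeric(t(val)))
  })
}
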