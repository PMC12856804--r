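# Kernel utilization distributions on a planar km grid, Bhattacharyya
# affinity, the trip-randomization segregation test, and sample
# representativeness.

#' Build a shared planar analysis grid
#'
#' Projects all supplied fixes into an azimuthal equidistant plane centred
#' on `center` and lays a square grid of `cell_km` cells over their bounding
#' box padded by `pad_km` (three bandwidths is the usual padding so kernels
#' are not clipped). Every UD compared in one analysis must share a grid.
#'
#' @param fixes Fix tibble with `lon`, `lat` (all groups pooled).
#' @param center `c(lon, lat)` of the projection centre; defaults to the
#'   fixes' centroid.
#' @param cell_km Grid cell size, km.
#' @param pad_km Padding around the bounding box, km.
#' @return List of class `ud_grid_spec`: `x`, `y` cell-centre coordinates
#'   (km), `cell_km`, `center`.
#' @export
make_grid <- function(fixes, center = NULL, cell_km = 10, pad_km = 3 * 105) {
  stopifnot(nrow(fixes) > 0, cell_km > 0)
  if (is.null(center)) {
    center <- c(mean(range(fixes$lon)), mean(range(fixes$lat)))
  }
  p <- project_aeqd(fixes, center)
  xr <- range(p$x) + c(-1, 1) * pad_km
  yr <- range(p$y) + c(-1, 1) * pad_km
  gx <- seq(floor(xr[1] / cell_km) * cell_km + cell_km / 2, xr[2],
            by = cell_km)
  gy <- seq(floor(yr[1] / cell_km) * cell_km + cell_km / 2, yr[2],
            by = cell_km)
  structure(list(x = gx, y = gy, cell_km = cell_km, center = center),
            class = "ud_grid_spec")
}

# KDE of planar points on the grid as a probability vector (column-major
# over (x, y)); separable Gaussian kernel, normalized to sum 1.
.kde_vec <- function(px, py, grid, bw_km) {
  nx <- length(grid$x); ny <- length(grid$y)
  z <- matrix(0, nx, ny)
  for (i in seq_along(px)) {
    z <- z + outer(stats::dnorm(grid$x, px[i], bw_km),
                   stats::dnorm(grid$y, py[i], bw_km))
  }
  s <- sum(z)
  if (s <= 0) rlang::abort("Kernel mass vanished on the grid; expand it.")
  as.numeric(z / s)
}

.new_ud <- function(p, grid) {
  structure(list(p = matrix(p, length(grid$x), length(grid$y)), grid = grid),
            class = "ud_grid")
}

#' Kernel utilization distribution of a set of fixes
#'
#' Isotropic bivariate Gaussian kernel with SD `bw_km` (the stage smoothing
#' parameter, in km) evaluated at the grid cell centres and normalized so
#' the cell masses sum to 1. If any fix lies within three bandwidths of the
#' grid edge the grid is expanded automatically with a warning.
#'
#' @param fixes Fix tibble with `lon`, `lat` (one trip, one bird, or a
#'   pooled set).
#' @param grid A [make_grid()] spec.
#' @param bw_km Kernel SD, km. Stage conventions used by the package:
#'   105 (incubation), 60 (brood guard), 105 (postguard).
#' @return Object of class `ud_grid`: cell-probability matrix plus its grid.
#' @export
kde_ud <- function(fixes, grid, bw_km) {
  stopifnot(nrow(fixes) >= 1, bw_km > 0)
  p <- project_aeqd(fixes, grid$center)
  half <- grid$cell_km / 2
  if (min(p$x) < min(grid$x) - half - 3 * bw_km ||
      max(p$x) > max(grid$x) + half + 3 * bw_km ||
      min(p$y) < min(grid$y) - half - 3 * bw_km ||
      max(p$y) > max(grid$y) + half + 3 * bw_km) {
    rlang::warn("Fixes fall outside the grid + 3 bandwidths; expanding.")
    grid <- make_grid(fixes, center = grid$center, cell_km = grid$cell_km,
                      pad_km = 3 * bw_km)
  }
  .new_ud(.kde_vec(p$x, p$y, grid, bw_km), grid)
}

#' Average trip-level UDs into a population UD
#'
#' Unweighted arithmetic mean over trips on their shared grid, renormalized.
#' The trip (not the bird) is the aggregation unit, matching the unit of the
#' randomization test.
#'
#' @param uds List of `ud_grid` objects on one grid.
#' @return A `ud_grid`.
#' @export
population_ud <- function(uds) {
  stopifnot(length(uds) >= 1)
  ref <- uds[[1]]$grid
  mats <- lapply(uds, function(u) {
    if (!isTRUE(all.equal(u$grid$x, ref$x)) ||
        !isTRUE(all.equal(u$grid$y, ref$y))) {
      rlang::abort("All UDs must share one grid; rebuild with a common grid.")
    }
    u$p
  })
  m <- Reduce(`+`, mats) / length(mats)
  .new_ud(as.numeric(m / sum(m)), ref)
}

#' Minimal top-density isopleth of a UD
#'
#' Sorts cells by density (stable tie-break on cell index) and takes the
#' shortest prefix whose cumulative mass reaches `level`: the 0.5 isopleth
#' is the core foraging area, 0.95 the home range.
#'
#' @param ud A `ud_grid`.
#' @param level Probability level in (0, 1).
#' @return List of class `isopleth`: `level`, logical `mask` matrix,
#'   `contained` mass.
#' @export
isopleth <- function(ud, level) {
  stopifnot(level > 0, level < 1)
  p <- as.numeric(ud$p)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= level)[1]
  mask <- logical(length(p))
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(level = level,
                 mask = matrix(mask, nrow(ud$p), ncol(ud$p)),
                 contained = cum[k], grid = ud$grid),
            class = "isopleth")
}

#' Bhattacharyya affinity between two UDs
#'
#' `sum over cells of sqrt(pA * pB)`: 1 for identical distributions, 0 for
#' disjoint supports. Both UDs must live on the same grid.
#'
#' @param ud_a,ud_b `ud_grid` objects on one grid.
#' @return Scalar in [0, 1].
#' @export
bhattacharyya <- function(ud_a, ud_b) {
  if (!identical(dim(ud_a$p), dim(ud_b$p))) {
    rlang::abort("UDs are on different grids.")
  }
  sum(sqrt(ud_a$p * ud_b$p))
}

#' Bhattacharyya affinity restricted to an isopleth level
#'
#' Each UD is renormalized within its own minimal top-density set at
#' `level` (zero outside) before computing affinity, comparing core areas
#' with core areas rather than whole surfaces.
#'
#' @inheritParams bhattacharyya
#' @param level Isopleth level, e.g. 0.5 for core areas.
#' @return Scalar in [0, 1].
#' @export
bhattacharyya_isopleth <- function(ud_a, ud_b, level) {
  clip <- function(u) {
    m <- isopleth(u, level)$mask
    p <- u$p * m
    .new_ud(as.numeric(p / sum(p)), u$grid)
  }
  bhattacharyya(clip(ud_a), clip(ud_b))
}

# per-trip UD matrix (n_trips x n_cells) for a trip tibble with a fixes
# list-column, on a shared grid
.trip_ud_matrix <- function(trips, grid, bw_km) {
  mat <- matrix(0, nrow(trips), length(grid$x) * length(grid$y))
  for (i in seq_len(nrow(trips))) {
    fx <- project_aeqd(trips$fixes[[i]], grid$center)
    mat[i, ] <- .kde_vec(fx$x, fx$y, grid, bw_km)
  }
  mat
}

#' Trip-randomization test of spatial segregation
#'
#' Computes the observed Bhattacharyya affinity between the two colonies'
#' population UDs, then repeatedly reassigns whole trips at random to the
#' two colonies (preserving group sizes), recomputing the population UDs
#' and affinity each time. The p-value is the proportion of randomized
#' affinities smaller than the observed one: a small p means the observed
#' overlap is lower (the colonies more segregated) than expected if trips
#' were exchangeable.
#'
#' @param trips_a,trips_b Trip tibbles (from [split_trips()]) for the two
#'   colonies, each with a `fixes` list-column.
#' @param bw_km Kernel SD, km.
#' @param cell_km Grid cell size, km.
#' @param n_iter Number of random reassignments.
#' @param seed Integer seed for the reassignments.
#' @param level Optional isopleth level; when given, affinities are
#'   computed on UDs renormalized within that level's top-density set.
#' @param plus_one Use the (b+1)/(n+1) p-value variant instead of the plain
#'   proportion.
#' @param grid Optional pre-built [make_grid()] spec.
#' @return Object of class `overlap_result`: `observed_ba`, `null_ba`,
#'   `p_value`, `n_iter`, `seed`, group sizes.
#' @export
segregation_test <- function(trips_a, trips_b, bw_km = 105, cell_km = 10,
                             n_iter = 1000, seed = 1, level = NULL,
                             plus_one = FALSE, grid = NULL) {
  stopifnot(nrow(trips_a) >= 2, nrow(trips_b) >= 2)
  if (n_iter < 100) {
    rlang::warn("Fewer than 100 randomizations gives an unstable p-value.")
  }
  all_fixes <- dplyr::bind_rows(c(trips_a$fixes, trips_b$fixes))
  if (is.null(grid)) {
    grid <- make_grid(all_fixes, cell_km = cell_km, pad_km = 3 * bw_km)
  }
  trips <- dplyr::bind_rows(trips_a, trips_b)
  n_a <- nrow(trips_a); n_b <- nrow(trips_b); n <- n_a + n_b
  tm <- .trip_ud_matrix(trips, grid, bw_km)

  ba_of <- function(idx_a) {
    pa <- colMeans(tm[idx_a, , drop = FALSE])
    pb <- colMeans(tm[-idx_a, , drop = FALSE])
    if (is.null(level)) {
      sum(sqrt(pa * pb))
    } else {
      bhattacharyya_isopleth(.new_ud(pa / sum(pa), grid),
                             .new_ud(pb / sum(pb), grid), level)
    }
  }
  observed <- ba_of(seq_len(n_a))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_ba <- numeric(n_iter)
  if (is.null(level)) {
    # vectorized: chunked permutation-indicator matrices against the
    # trip-UD matrix
    chunk <- 200L
    done <- 0L
    while (done < n_iter) {
      m <- min(chunk, n_iter - done)
      ind <- matrix(0, m, n)
      for (r in seq_len(m)) ind[r, sample.int(n, n_a)] <- 1
      pa <- (ind %*% tm) / n_a
      pb <- ((1 - ind) %*% tm) / n_b
      null_ba[done + seq_len(m)] <- rowSums(sqrt(pa * pb))
      done <- done + m
    }
  } else {
    for (r in seq_len(n_iter)) null_ba[r] <- ba_of(sample.int(n, n_a))
  }
  p <- if (plus_one) {
    (sum(null_ba < observed) + 1) / (n_iter + 1)
  } else {
    sum(null_ba < observed) / n_iter
  }
  structure(list(observed_ba = observed, null_ba = null_ba, p_value = p,
                 n_iter = n_iter, seed = seed, n_a = n_a, n_b = n_b,
                 level = level, plus_one = plus_one, grid = grid),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Trip-randomization segregation test\n")
  cat(sprintf("  groups: %d vs %d trips;  %d randomizations (seed %d)\n",
              x$n_a, x$n_b, x$n_iter, x$seed))
  if (!is.null(x$level)) {
    cat(sprintf("  affinity restricted to the %.0f%% isopleth\n",
                100 * x$level))
  }
  cat(sprintf("  observed BA = %.4f;  null mean = %.4f;  p = %.4g\n",
              x$observed_ba, mean(x$null_ba), x$p_value))
  invisible(x)
}

#' Tidy / glance methods for segregation test results
#'
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per randomization; `glance()`: one-row summary.
#' @exportS3Method generics::tidy
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n_iter), null_ba = x$null_ba)
}

#' @rdname tidy.overlap_result
#' @exportS3Method generics::glance
glance.overlap_result <- function(x, ...) {
  tibble::tibble(observed_ba = x$observed_ba, p_value = x$p_value,
                 null_mean = mean(x$null_ba), n_iter = x$n_iter,
                 n_a = x$n_a, n_b = x$n_b, seed = x$seed)
}

#' Representativeness of a trip sample
#'
#' For each subsample size s = 1..N-1, draws `n_boot` random subsets of
#' trips, pools them into a UD, and scores the fraction of the left-out
#' trips' fixes that fall inside the subset's 50% core-area isopleth. The
#' mean inclusion curve is fit with a saturating hyperbola
#' `y = a s / (b + s)`; the statistic returned is the fitted inclusion at
#' s = N as a percentage of the asymptote `a`, capped at 100: how much of
#' the population core the tracked sample captured.
#'
#' @param trips Trip tibble with a `fixes` list-column.
#' @param bw_km,cell_km Kernel SD and grid cell size, km.
#' @param n_boot Bootstrap draws per subsample size.
#' @param seed Integer seed.
#' @param level Isopleth level scored for inclusion.
#' @return List of class `representativeness`: `percent`, the inclusion
#'   curve tibble, fitted `a` and `b`, and a low-confidence flag when there
#'   are fewer than three subsample sizes.
#' @export
representativeness <- function(trips, bw_km = 105, cell_km = 10,
                               n_boot = 50, seed = 1, level = 0.5) {
  n <- nrow(trips)
  stopifnot(n >= 2)
  grid <- make_grid(dplyr::bind_rows(trips$fixes), cell_km = cell_km,
                    pad_km = 3 * bw_km)
  tm <- .trip_ud_matrix(trips, grid, bw_km)
  # cell index of every fix, per trip
  cell_of <- lapply(trips$fixes, function(fx) {
    p <- project_aeqd(fx, grid$center)
    ix <- findInterval(p$x, grid$x - grid$cell_km / 2)
    iy <- findInterval(p$y, grid$y - grid$cell_km / 2)
    ok <- ix >= 1 & ix <= length(grid$x) & iy >= 1 & iy <= length(grid$y)
    (iy[ok] - 1L) * length(grid$x) + ix[ok]
  })
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sizes <- seq_len(n - 1)
  curve <- purrr::map_dfr(sizes, function(s) {
    incl <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, s)
      pooled <- colMeans(tm[idx, , drop = FALSE])
      mask <- as.numeric(isopleth(.new_ud(pooled / sum(pooled), grid),
                                  level)$mask)
      cells <- unlist(cell_of[-idx])
      if (length(cells) == 0) return(NA_real_)
      mean(mask[cells] > 0)
    }, numeric(1))
    tibble::tibble(size = s, inclusion = mean(incl, na.rm = TRUE))
  })
  low_confidence <- length(sizes) < 3
  if (low_confidence) {
    pct <- min(100, 100 * curve$inclusion[nrow(curve)])
    a <- NA_real_; b <- NA_real_
    rlang::warn(
      "Too few subsample sizes to fit an asymptote; reporting raw inclusion.")
  } else {
    fit <- stats::optim(
      c(a = max(curve$inclusion), b = 1),
      function(par) {
        sum((curve$inclusion - par[1] * curve$size / (par[2] + curve$size))^2)
      },
      method = "L-BFGS-B", lower = c(1e-6, 1e-6), upper = c(1.5, 1e3))
    a <- fit$par[1]; b <- fit$par[2]
    pct <- min(100, 100 * (a * n / (b + n)) / a)
  }
  structure(list(percent = pct, curve = curve, a = unname(a), b = unname(b),
                 n_trips = n, low_confidence = low_confidence),
            class = "representativeness")
}

#' @export
print.representativeness <- function(x, ...) {
  cat(sprintf("Sample representativeness: %.1f%% of the population core (%d trips%s)\n",
              x$percent, x$n_trips,
              if (x$low_confidence) "; low confidence" else ""))
  invisible(x)
}

#' Per-bird core foraging areas
#'
#' Pools each bird's trips into one UD, extracts its `level` isopleth, and
#' counts per grid cell how many birds' cores cover it: a direct check on
#' whether population-specific areas are used by multiple individuals.
#'
#' @param trips Trip tibble with `bird_id` and a `fixes` list-column.
#' @param bw_km,cell_km Kernel SD and cell size, km.
#' @param level Isopleth level (0.5 = core foraging area).
#' @param grid Optional shared [make_grid()] spec.
#' @return List of class `core_areas`: per-bird tibble (`bird_id`,
#'   `n_core_cells`, `core` isopleth list-column), `bird_count` matrix,
#'   `grid`.
#' @export
individual_core_areas <- function(trips, bw_km = 105, cell_km = 10,
                                  level = 0.5, grid = NULL) {
  stopifnot(nrow(trips) >= 1)
  if (is.null(grid)) {
    grid <- make_grid(dplyr::bind_rows(trips$fixes), cell_km = cell_km,
                      pad_km = 3 * bw_km)
  }
  birds <- split(trips, trips$bird_id)
  per_bird <- purrr::map_dfr(names(birds), function(b) {
    fx <- dplyr::bind_rows(birds[[b]]$fixes)
    ud <- kde_ud(fx, grid, bw_km)
    iso <- isopleth(ud, level)
    tibble::tibble(bird_id = b, n_core_cells = sum(iso$mask),
                   core = list(iso))
  })
  counts <- Reduce(`+`, lapply(per_bird$core, function(i) i$mask * 1))
  structure(list(per_bird = per_bird, bird_count = counts, grid = grid),
            class = "core_areas")
}

#' Tidy a UD grid into a long tibble
#'
#' @param x A `ud_grid`.
#' @param ... Unused.
#' @return Tibble with planar `x`, `y` (km), `lon`, `lat` of cell centres
#'   and the cell probability mass `p`.
#' @exportS3Method generics::tidy
tidy.ud_grid <- function(x, ...) {
  g <- x$grid
  df <- tidyr::expand_grid(y = g$y, x = g$x) |>
    dplyr::relocate("x")
  ll <- unproject_aeqd(df$x, df$y, g$center)
  df$lon <- ll$lon
  df$lat <- ll$lat
  df$p <- as.numeric(x$p[cbind(match(df$x, g$x), match(df$y, g$y))])
  df
}

#' Export UD isopleths as GeoJSON polygons
#'
#' Writes each selected grid cell of each requested isopleth as an
#' unprojected WGS84 polygon feature with `level` and `contained`
#' properties.
#'
#' @param ud A `ud_grid`.
#' @param path Output file path.
#' @param levels Isopleth levels to export.
#' @return `path`, invisibly.
#' @export
write_isopleth_geojson <- function(ud, path, levels = c(0.5, 0.95)) {
  g <- ud$grid
  half <- g$cell_km / 2
  feats <- character(0)
  for (lev in levels) {
    iso <- isopleth(ud, lev)
    idx <- which(iso$mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      cx <- g$x[idx[r, 1]]; cy <- g$y[idx[r, 2]]
      corners <- unproject_aeqd(cx + c(-half, half, half, -half, -half),
                                cy + c(-half, -half, half, half, -half),
                                g$center)
      ring <- paste(sprintf("[%.6f,%.6f]", corners$lon, corners$lat),
                    collapse = ",")
      feats <- c(feats, sprintf(
        '{"type":"Feature","properties":{"level":%g,"contained":%.6f},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
        lev, iso$contained, ring))
    }
  }
  txt <- paste0('{"type":"FeatureCollection","features":[',
                paste(feats, collapse = ","), "]}")
  writeLines(txt, path)
  invisible(path)
}
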