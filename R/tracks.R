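# Cleaning and regularizing raw fixes, splitting colony-anchored trips,
# inferring breeding stage, and computing trip summary statistics.

.check_fixes <- function(fixes) {
  need <- c("bird_id", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(fixes))
  if (length(miss) > 0) {
    rlang::abort(paste0("Fix table lacks columns: ",
                        paste(miss, collapse = ", ")))
  }
  .check_lonlat(fixes$lon, fixes$lat, "fix coordinates")
  invisible(TRUE)
}

#' Remove fixes implying implausible travel speeds
#'
#' Sequential root-removal per bird: the first fix is kept; each subsequent
#' fix is dropped when the speed implied from the previous *kept* fix exceeds
#' `vmax_kmh`. A single displaced fix therefore removes exactly itself (a
#' pairwise rule would also delete its innocent neighbour).
#'
#' @param fixes Fix tibble (`bird_id`, `timestamp`, `lat`, `lon`, ...),
#'   time-ordered within bird.
#' @param vmax_kmh Speed ceiling, km/h.
#' @return The kept fixes; the removed rows are attached as
#'   `attr(, "removed")`.
#' @export
speed_filter <- function(fixes, vmax_kmh = 80) {
  .check_fixes(fixes)
  res <- fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      if (anyDuplicated(df$timestamp)) {
        rlang::abort(paste0("Duplicate timestamps for bird ", key$bird_id))
      }
      if (is.unsorted(df$timestamp)) {
        rlang::abort(paste0("Timestamps not increasing for bird ",
                            key$bird_id))
      }
      n <- nrow(df)
      keep <- logical(n)
      keep[1] <- TRUE
      last <- 1L
      for (i in seq_len(n)[-1]) {
        dt <- as.numeric(difftime(df$timestamp[i], df$timestamp[last],
                                  units = "hours"))
        d <- great_circle_km(df$lon[last], df$lat[last],
                             df$lon[i], df$lat[i])
        if (dt > 0 && d / dt <= vmax_kmh) {
          keep[i] <- TRUE
          last <- i
        }
      }
      dplyr::mutate(df, .keep_fix = keep)
    }) |>
    dplyr::ungroup()
  kept <- dplyr::select(dplyr::filter(res, .data$.keep_fix), -".keep_fix")
  removed <- dplyr::select(dplyr::filter(res, !.data$.keep_fix), -".keep_fix")
  attr(kept, "removed") <- removed
  kept
}

#' Regularize fixes to a fixed time interval
#'
#' Linear interpolation of latitude and longitude at exact interval marks
#' (on the whole-hour grid for the default 1 h) between each bird's first
#' and last fix. Gaps longer than `max_gap_h` are left unfilled rather than
#' interpolated across.
#'
#' @inheritParams speed_filter
#' @param interval_h Output interval, hours.
#' @param max_gap_h Longest gap (hours) across which to interpolate.
#' @return Regularized fix tibble with the interval marks as timestamps.
#'   Character metadata columns constant within bird (e.g. `colony`) are
#'   carried along.
#' @export
regularize <- function(fixes, interval_h = 1, max_gap_h = 12) {
  .check_fixes(fixes)
  carry <- intersect(c("colony", "trip_id", "stage_true"), names(fixes))
  fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      t0 <- as.numeric(df$timestamp[1])
      step <- interval_h * 3600
      start <- ceiling(t0 / step) * step
      tn <- as.numeric(df$timestamp[nrow(df)])
      if (start > tn) return(df[0, ])
      marks <- seq(start, floor(tn / step) * step, by = step)
      tt <- as.numeric(df$timestamp)
      idx <- findInterval(marks, tt)
      idx <- pmin(pmax(idx, 1L), nrow(df) - 1L)
      gap <- tt[idx + 1L] - tt[idx]
      # marks coinciding with a raw fix are kept even beside a long gap
      exact <- marks == tt[idx] | marks == tt[idx + 1L]
      ok <- (gap <= max_gap_h * 3600 | exact) &
        marks >= tt[idx] & marks <= tt[idx + 1L]
      frac <- ifelse(gap > 0, (marks - tt[idx]) / gap, 0)
      out <- tibble::tibble(
        timestamp = as.POSIXct(marks, origin = "1970-01-01", tz = "UTC"),
        lat = df$lat[idx] + frac * (df$lat[idx + 1L] - df$lat[idx]),
        lon = df$lon[idx] + frac * (df$lon[idx + 1L] - df$lon[idx])
      )[ok, ]
      for (cc in carry) {
        out[[cc]] <- df[[cc]][idx][ok]
      }
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::any_of(c("bird_id", "colony")), "timestamp")
}

#' Split a bird's fixes into colony-anchored foraging trips
#'
#' A trip runs from the last fix inside the colony buffer before an excursion
#' to the first fix back inside it. Excursions shorter than `min_trip_h` or
#' that never leave the buffer are discarded; a terminal excursion with no
#' return is kept with `complete = FALSE`.
#'
#' @inheritParams speed_filter
#' @param colony One-row tibble with `colony`, `lat`, `lon`, `buffer_km`
#'   (see [default_colonies()]); fixes are split against this colony.
#' @param min_trip_h Minimum excursion duration to count as a trip, hours.
#' @return Trip tibble: `trip_id`, `bird_id`, `colony`, `complete`,
#'   `start`, `end`, `n_fixes`, and a `fixes` list-column of fix tibbles.
#' @export
split_trips <- function(fixes, colony, min_trip_h = 6) {
  .check_fixes(fixes)
  stopifnot(nrow(colony) == 1, colony$buffer_km > 0)
  fixes$.at_colony <- great_circle_km(colony$lon, colony$lat,
                                      fixes$lon, fixes$lat) <=
    colony$buffer_km
  if (!any(fixes$.at_colony)) {
    rlang::warn("No fixes inside the colony buffer; zero trips returned.")
  }
  trips <- fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_map(function(df, key) {
      at <- df$.at_colony
      n <- nrow(df)
      inside <- which(at)
      if (length(inside) == 0) return(NULL)
      out <- list()
      i <- inside[1]
      while (i < n) {
        # advance to the last inside fix before the next excursion
        j <- i
        while (j < n && at[j + 1L]) j <- j + 1L
        if (j >= n) break
        ret <- j + 1L
        while (ret <= n && !at[ret]) ret <- ret + 1L
        complete <- ret <= n
        last_fix <- if (complete) ret else n
        seg <- df[j:last_fix, ]
        dur <- as.numeric(difftime(seg$timestamp[nrow(seg)],
                                   seg$timestamp[1], units = "hours"))
        if (dur >= min_trip_h && nrow(seg) >= 2) {
          out[[length(out) + 1]] <- tibble::tibble(
            bird_id = key$bird_id,
            colony = colony$colony,
            complete = complete,
            start = seg$timestamp[1],
            end = seg$timestamp[nrow(seg)],
            n_fixes = nrow(seg),
            fixes = list(dplyr::select(seg, -".at_colony"))
          )
        }
        if (!complete) break
        i <- ret
      }
      if (length(out) == 0) NULL else dplyr::bind_rows(out)
    }) |>
    dplyr::bind_rows()
  if (nrow(trips) == 0) {
    return(tibble::tibble(trip_id = character(), bird_id = character(),
                          colony = character(), complete = logical(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          n_fixes = integer(), fixes = list()))
  }
  trips |>
    dplyr::arrange(.data$bird_id, .data$start) |>
    dplyr::mutate(trip_id = sprintf("%s_%03d", .data$bird_id,
                                    dplyr::row_number()),
                  .by = "bird_id") |>
    dplyr::relocate("trip_id")
}

#' Assign breeding stages to trips
#'
#' Trips are first matched to the stage windows their time span overlaps.
#' Where windows themselves overlap (the brood-guard window overlaps both
#' neighbours in March and April) the post-trip colony attendance decides:
#' attendance longer than `attendance_h` after the trip points to the
#' earlier stage (incubation or brood guard shifts), otherwise the later.
#' Attendance is measured as the gap between a trip's end and the same
#' bird's next trip start; for a bird's final trip it is unknown and the
#' later stage is assigned.
#'
#' @param trips Trip tibble from [split_trips()].
#' @param windows Stage calendar from [stage_windows()].
#' @param attendance_h Attendance threshold, hours.
#' @return `trips` with a `stage` column.
#' @export
infer_stage <- function(trips, windows = stage_windows(),
                        attendance_h = 12) {
  if (nrow(trips) == 0) return(dplyr::mutate(trips, stage = character(0)))
  windows <- dplyr::arrange(windows, .data$start)
  trips <- trips |>
    dplyr::arrange(.data$bird_id, .data$start) |>
    dplyr::mutate(
      next_start = dplyr::lead(.data$start), .by = "bird_id") |>
    dplyr::mutate(attendance = as.numeric(difftime(.data$next_start,
                                                   .data$end,
                                                   units = "hours")))
  stage <- character(nrow(trips))
  for (i in seq_len(nrow(trips))) {
    hits <- which(trips$start[i] < windows$end & trips$end[i] >= windows$start)
    if (length(hits) == 0) {
      stage[i] <- NA_character_
    } else if (length(hits) == 1) {
      stage[i] <- windows$stage[hits]
    } else {
      att <- trips$attendance[i]
      earlier <- hits[1]; later <- hits[length(hits)]
      stage[i] <- if (!is.na(att) && att > attendance_h) {
        windows$stage[earlier]
      } else {
        windows$stage[later]
      }
    }
  }
  if (anyNA(stage)) {
    rlang::warn("Some trips fall outside every stage window (stage = NA).")
  }
  trips |>
    dplyr::mutate(stage = stage) |>
    dplyr::select(-"next_start", -"attendance")
}

#' Per-trip summary metrics
#'
#' Duration (h), total distance travelled (sum of great-circle legs, km),
#' foraging range (maximum great-circle distance from the colony, km) and
#' the initial bearing from the colony to the farthest fix (degrees).
#'
#' @param trips Trip tibble from [split_trips()] (optionally staged).
#' @param colony One-row colony tibble.
#' @return `trips` without the `fixes` column, plus `duration_h`,
#'   `total_distance_km`, `foraging_range_km`, `bearing_far_deg`.
#' @export
trip_metrics <- function(trips, colony) {
  stopifnot(nrow(colony) == 1)
  met <- purrr::map_dfr(trips$fixes, function(fx) {
    n <- nrow(fx)
    legs <- if (n >= 2) {
      great_circle_km(fx$lon[-n], fx$lat[-n], fx$lon[-1], fx$lat[-1])
    } else 0
    dcol <- great_circle_km(colony$lon, colony$lat, fx$lon, fx$lat)
    far <- which.max(dcol)
    bearing <- if (dcol[far] > 1e-9) {
      initial_bearing(colony$lon, colony$lat, fx$lon[far], fx$lat[far])
    } else NA_real_
    tibble::tibble(
      duration_h = as.numeric(difftime(fx$timestamp[n], fx$timestamp[1],
                                       units = "hours")),
      total_distance_km = sum(legs),
      foraging_range_km = dcol[far],
      bearing_far_deg = bearing
    )
  })
  dplyr::bind_cols(dplyr::select(trips, -"fixes"), met)
}

#' Stage-by-colony summary of completed trips
#'
#' Means and SDs of the per-trip metrics, restricted to complete trips
#' (including incomplete trips would bias the summaries, since they are
#' truncated at an arbitrary point).
#'
#' @param metrics Output of [trip_metrics()], with a `stage` column.
#' @return Tibble with one row per colony-stage.
#' @export
trip_summary <- function(metrics) {
  metrics |>
    dplyr::filter(.data$complete) |>
    dplyr::group_by(.data$colony, .data$stage) |>
    dplyr::summarise(
      n_birds = dplyr::n_distinct(.data$bird_id),
      n_trips = dplyr::n(),
      duration_sd = stats::sd(.data$duration_h),
      duration_h = mean(.data$duration_h),
      distance_km = mean(.data$total_distance_km),
      distance_sd = stats::sd(.data$total_distance_km),
      range_km = mean(.data$foraging_range_km),
      range_sd = stats::sd(.data$foraging_range_km),
      bearing_deg = circular_mean_sd(.data$bearing_far_deg)$mean_deg,
      .groups = "drop"
    ) |>
    dplyr::relocate("duration_h", .before = "duration_sd")
}

#' Read and write the five-column track CSV schema
#'
#' `bird_id, colony, timestamp, lat, lon` with ISO-8601 UTC timestamps.
#'
#' @param path File path.
#' @return `read_tracks_csv()`: a fix tibble.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  tibble::as_tibble(df)
}

#' @rdname read_tracks_csv
#' @param tracks Fix tibble.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- dplyr::select(tracks, "bird_id", "colony", "timestamp",
                       "lat", "lon")
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
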