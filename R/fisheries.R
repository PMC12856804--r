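# Grid-based overlap between colony time distributions and fishing effort.
# Cells are half-open 1-degree bins [k, k+1) in both axes, identified by
# their centres (k + 0.5); boundary fixes fall in the lower-left cell.

GEAR_TYPES <- c("drifting_longline", "set_longline", "trawler",
                "squid_jigger", "pole_and_line", "unknown")

.cell_center <- function(x) floor(x) + 0.5

#' Proportion of colony time per one-degree cell
#'
#' Counts regularized (equal-interval) fixes per 1-degree cell within a
#' stage window, normalized to sum to 1 over the colony-stage: with hourly
#' fixes, counts are proportional to time spent. Overlapping stage windows
#' mean a fix can contribute to more than one stage; the shares within each
#' stage still sum to 1.
#'
#' @param fixes Regularized fix tibble for one colony (`timestamp`, `lat`,
#'   `lon`).
#' @param window One row of [stage_windows()] (half-open `[start, end)`).
#' @return Tibble `lat_center`, `lon_center`, `share`.
#' @export
time_share <- function(fixes, window) {
  stopifnot(nrow(window) == 1)
  sel <- fixes$timestamp >= window$start & fixes$timestamp < window$end
  if (!any(sel)) {
    rlang::warn("No fixes in the stage window; empty share grid.")
    return(tibble::tibble(lat_center = numeric(), lon_center = numeric(),
                          share = numeric()))
  }
  fixes[sel, ] |>
    dplyr::count(lat_center = .cell_center(.data$lat),
                 lon_center = .cell_center(.data$lon), name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::select("lat_center", "lon_center", "share")
}

#' Overlap index between a time-share grid and an effort grid
#'
#' The index is the sum over cells of (proportion of colony time in the
#' cell) x (hours fished in the cell): a relative exposure measure, not a
#' bycatch rate. Per-cell contributions are returned for mapping.
#'
#' @param shares Output of [time_share()].
#' @param effort Effort tibble (`lat_center`, `lon_center`, `hours`);
#'   multiple rows per cell (gears, flags) are summed.
#' @return List: `index` (scalar) and `cells`, a tibble of per-cell
#'   contributions.
#' @export
overlap_index <- function(shares, effort) {
  eff <- effort |>
    dplyr::group_by(.data$lat_center, .data$lon_center) |>
    dplyr::summarise(hours = sum(.data$hours), .groups = "drop")
  cells <- dplyr::inner_join(shares, eff,
                             by = c("lat_center", "lon_center")) |>
    dplyr::mutate(contribution = .data$share * .data$hours)
  list(index = sum(cells$contribution), cells = cells)
}

#' Overlap indices disaggregated by stage, gear and flag
#'
#' For each colony and stage, computes the overlap index for every gear,
#' every flag-gear combination, and all fishing combined, plus a per-colony
#' total over stages. The stage windows differ in length, so values compare
#' across colonies but not across stages (recorded in the `caveat`
#' attribute).
#'
#' @param fixes Regularized fix tibble with a `colony` column.
#' @param effort Effort tibble `lat_center`, `lon_center`, `flag`, `gear`,
#'   `stage`, `hours`.
#' @param windows Stage calendar from [stage_windows()].
#' @return Tibble `colony`, `stage`, `gear`, `flag`, `index`; `gear`/`flag`
#'   take the value `"all"` for aggregated rows and `stage = "total"` rows
#'   sum the per-stage all-fishing indices.
#' @export
overlap_by_group <- function(fixes, effort, windows = stage_windows()) {
  bad_gear <- setdiff(unique(effort$gear), GEAR_TYPES)
  if (length(bad_gear) > 0) {
    rlang::abort(paste0("Unknown gear type(s): ",
                        paste(bad_gear, collapse = ", ")))
  }
  rows <- list()
  for (col in unique(fixes$colony)) {
    cf <- dplyr::filter(fixes, .data$colony == col)
    for (i in seq_len(nrow(windows))) {
      st <- windows$stage[i]
      shares <- suppressWarnings(time_share(cf, windows[i, ]))
      eff <- dplyr::filter(effort, .data$stage == st)
      add <- function(gear, flag, e) {
        rows[[length(rows) + 1]] <<- tibble::tibble(
          colony = col, stage = st, gear = gear, flag = flag,
          index = if (nrow(shares) == 0 || nrow(e) == 0) 0
          else overlap_index(shares, e)$index)
      }
      add("all", "all", eff)
      for (g in unique(eff$gear)) {
        eg <- dplyr::filter(eff, .data$gear == g)
        add(g, "all", eg)
        for (fl in unique(eg$flag)) {
          add(g, fl, dplyr::filter(eg, .data$flag == fl))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  totals <- out |>
    dplyr::filter(.data$gear == "all", .data$flag == "all") |>
    dplyr::group_by(.data$colony) |>
    dplyr::summarise(stage = "total", gear = "all", flag = "all",
                     index = sum(.data$index), .groups = "drop")
  res <- dplyr::bind_rows(out, totals)
  attr(res, "caveat") <- paste(
    "Stage windows differ in duration; indices compare among colonies",
    "within a stage, not among stages.")
  res
}

#' Read/write the effort CSV schema
#'
#' `lat_center, lon_center, flag, gear, stage, hours`.
#'
#' @param path File path.
#' @return `read_effort_csv()`: effort tibble.
#' @export
read_effort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_effort_csv
#' @param effort Effort tibble.
#' @export
write_effort_csv <- function(effort, path) {
  utils::write.csv(effort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
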