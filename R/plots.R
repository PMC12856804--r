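# ggplot2 methods for the package's result objects.

#' Plot a utilization distribution
#'
#' Raster of cell masses in the planar analysis frame with the 50% and 95%
#' isopleth cells outlined by fill threshold contours.
#'
#' @param object A `ud_grid`.
#' @param levels Isopleth levels to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ud_grid <- function(object, levels = c(0.5, 0.95), ...) {
  df <- tidy(object)
  iso <- purrr::map(levels, function(l) isopleth(object, l))
  for (i in seq_along(levels)) {
    df[[paste0("iso_", i)]] <- as.numeric(iso[[i]]$mask)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$p)) +
    ggplot2::scale_fill_viridis_c(name = "UD mass") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east of centre", y = "km north of centre")
  for (i in seq_along(levels)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data[[paste0("iso_", i)]]),
      breaks = 0.5, colour = "white", linewidth = 0.3)
  }
  p
}

#' Plot a segregation-test null distribution
#'
#' Histogram of the randomized Bhattacharyya affinities with the observed
#' affinity marked; mass to the left of the line is the p-value.
#'
#' @param object An `overlap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_ba)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_ba, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "Bhattacharyya affinity under random trip assignment",
      y = "randomizations",
      title = sprintf("Observed BA = %.3f, p = %.3g",
                      object$observed_ba, object$p_value))
}

#' Plot a representativeness inclusion curve
#'
#' Mean out-of-sample inclusion against subsample size, with the fitted
#' saturating hyperbola when available.
#'
#' @param object A `representativeness` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.representativeness <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(.data$size, .data$inclusion)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trips in subsample", y = "out-of-sample inclusion",
                  title = sprintf("Representativeness: %.1f%%",
                                  object$percent))
  if (!is.na(object$a)) {
    grid <- tibble::tibble(size = seq(1, object$n_trips, length.out = 100))
    grid$inclusion <- object$a * grid$size / (object$b + grid$size)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Bar chart of overlap indices by gear and colony
#'
#' @param overlap Output of [overlap_by_group()].
#' @param stage_filter Stages to show (default: all but the totals row).
#' @return A ggplot.
#' @export
plot_overlap_table <- function(overlap,
                               stage_filter = setdiff(unique(overlap$stage),
                                                      "total")) {
  df <- overlap |>
    dplyr::filter(.data$flag == "all", .data$gear != "all",
                  .data$stage %in% stage_filter)
  ggplot2::ggplot(df, ggplot2::aes(.data$gear, .data$index,
                                   fill = .data$colony)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "overlap index (share x hours fished)")
}
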