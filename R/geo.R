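# Spherical geodesy on the mean Earth radius used throughout the package.

#' Mean Earth radius (km) used for all spherical geometry
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

.check_lonlat <- function(lon, lat, what = "coordinates") {
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    rlang::abort(paste0("Non-finite ", what, " supplied."))
  }
  if (any(lat < -90 | lat > 90)) {
    rlang::abort("Latitude outside [-90, 90].")
  }
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' points; inputs recycle as in base R.
#'
#' @param lon1,lat1 Origin longitude/latitude in decimal degrees.
#' @param lon2,lat2 Destination longitude/latitude in decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1) # one degree of latitude, ~111.2 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  .check_lonlat(lon1, lat1)
  .check_lonlat(lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial (forward) bearing between two points
#'
#' Forward azimuth from the first point to the second, clockwise from true
#' north, reported in [0, 360).
#'
#' @inheritParams great_circle_km
#' @return Bearing in degrees, in [0, 360).
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  .check_lonlat(lon1, lat1)
  .check_lonlat(lon2, lat2)
  same <- lon1 == lon2 & lat1 == lat2
  if (any(same)) {
    rlang::abort("Bearing undefined for coincident points.")
  }
  # great-circle forward azimuth in (-180, 180]; f = 0 forces the sphere,
  # keeping bearings consistent with the haversine distances
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2), f = 0)
  (b + 360) %% 360
}

#' Destination point along a great circle
#'
#' @inheritParams great_circle_km
#' @param bearing_deg Initial bearing in degrees clockwise from north.
#' @param distance_km Distance travelled along the great circle, km.
#' @return Tibble with columns `lon`, `lat`.
#' @export
destination_point <- function(lon1, lat1, bearing_deg, distance_km) {
  .check_lonlat(lon1, lat1)
  p <- geosphere::destPoint(cbind(lon1, lat1), bearing_deg,
                            distance_km * 1000, r = EARTH_RADIUS_KM * 1000)
  tibble::tibble(lon = ((p[, 1] + 180) %% 360) - 180, lat = p[, 2])
}

#' Azimuthal equidistant projection
#'
#' Projects lon/lat onto a plane centred on `center`, preserving distance and
#' bearing from the centre: a point d km from the centre at bearing theta maps
#' to (d sin theta, d cos theta). This makes kernel smoothing in km honest
#' near the colony region. `unproject()` inverts it; the round trip is exact
#' to well under a metre over foraging-range scales.
#'
#' @param df Data frame with `lon` and `lat` columns (degrees).
#' @param center Length-2 numeric `c(lon, lat)` of the projection centre.
#' @return `df` with planar `x`, `y` columns appended (km east/north of centre).
#' @export
project_aeqd <- function(df, center) {
  .check_lonlat(df$lon, df$lat)
  .check_lonlat(center[1], center[2], "projection centre")
  d <- great_circle_km(center[1], center[2], df$lon, df$lat)
  at_center <- d < 1e-9
  th <- numeric(nrow(df))
  if (any(!at_center)) {
    th[!at_center] <- initial_bearing(center[1], center[2],
                                      df$lon[!at_center], df$lat[!at_center])
  }
  dplyr::mutate(df,
                x = d * sin(th * pi / 180),
                y = d * cos(th * pi / 180))
}

#' @rdname project_aeqd
#' @param x,y Planar km coordinates relative to the centre.
#' @return `unproject_aeqd()`: tibble with `lon`, `lat` columns.
#' @export
unproject_aeqd <- function(x, y, center) {
  d <- sqrt(x^2 + y^2)
  th <- (atan2(x, y) * 180 / pi) %% 360
  out <- destination_point(center[1], center[2], th, d)
  out$lon[d < 1e-12] <- center[1]
  out$lat[d < 1e-12] <- center[2]
  out
}
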