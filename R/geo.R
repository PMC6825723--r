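# Spherical geometry on a mean-Earth-radius sphere.  An ellipsoidal model
# buys <0.5% at the 15-km scale this package works on; the geodesic oracle
# used to bound that error lives in the test suite.

#' Mean Earth radius (km) used by all spherical computations
#'
#' IUGG mean radius R1 = 6371.0088 km.
#' @export
EARTH_RADIUS_KM <- 6371.0088

check_coords <- function(lat, lon, what = "coordinate") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop(what, ": non-finite latitude/longitude", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop(what, ": latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop(what, ": longitude outside [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle (haversine) distance in kilometres
#'
#' Distance on a sphere of radius [EARTH_RADIUS_KM]. Vectorised over all
#' four arguments (recycled).
#'
#' @param lat1,lon1 first point(s), degrees WGS84
#' @param lat2,lon2 second point(s), degrees WGS84
#' @return numeric vector of distances in km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1, "point a")
  check_coords(lat2, lon2, "point b")
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing, radians from north
#' @keywords internal
bearing_rad <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  dlam <- (lon2 - lon1) * rad
  atan2(sin(dlam) * cos(p2),
        cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam))
}

#' Project fixes onto a local azimuthal-equidistant plane
#'
#' Projection centred at `origin`; distances from the origin are preserved
#' exactly (by construction), so hull areas and ranges computed on the
#' plane are faithful for the <= 15 km scale of habitual mobility.
#'
#' @param lat,lon points to project, degrees
#' @param origin_lat,origin_lon projection centre (typically home), degrees
#' @param max_km points farther than this from the origin raise an error
#'   (callers are expected to home-filter first)
#' @return data.frame with columns `x_km`, `y_km` (east, north)
#' @seealso [unproject_local()]
#' @export
project_local <- function(lat, lon, origin_lat, origin_lon, max_km = 100) {
  check_coords(origin_lat, origin_lon, "origin")
  check_coords(lat, lon, "fix")
  d <- haversine_km(origin_lat, origin_lon, lat, lon)
  if (any(d > max_km))
    stop("project_local: point ", which.max(d > max_km), " lies ",
         format(max(d), digits = 4), " km from origin (limit ", max_km,
         " km); filter first", call. = FALSE)
  th <- bearing_rad(origin_lat, origin_lon, lat, lon)
  data.frame(x_km = d * sin(th), y_km = d * cos(th))
}

#' Inverse of [project_local()]
#'
#' @param x_km,y_km local planar coordinates (east, north) in km
#' @param origin_lat,origin_lon projection centre, degrees
#' @return data.frame with columns `lat`, `lon`
#' @export
unproject_local <- function(x_km, y_km, origin_lat, origin_lon) {
  check_coords(origin_lat, origin_lon, "origin")
  rad <- pi / 180
  d <- sqrt(x_km^2 + y_km^2)
  th <- atan2(x_km, y_km)
  delta <- d / EARTH_RADIUS_KM
  p1 <- origin_lat * rad
  p2 <- asin(sin(p1) * cos(delta) + cos(p1) * sin(delta) * cos(th))
  lam <- origin_lon * rad +
    atan2(sin(th) * sin(delta) * cos(p1), cos(delta) - sin(p1) * sin(p2))
  out <- data.frame(lat = p2 / rad, lon = lam / rad)
  out$lon <- ((out$lon + 180) %% 360) - 180
  out
}

#' Keep only fixes within a radius of home
#'
#' Habitual-mobility filter: retains fixes whose great-circle distance to
#' home is at most `radius_km` (boundary inclusive). Order is preserved.
#'
#' @param fixes data.frame with `lat`, `lon` columns (other columns kept)
#' @param home_lat,home_lon home coordinates, degrees
#' @param radius_km cutoff, default 15 km
#' @return the retained rows of `fixes`
#' @export
filter_home_radius <- function(fixes, home_lat, home_lon, radius_km = 15) {
  if (nrow(fixes) == 0L) return(fixes)
  d <- haversine_km(home_lat, home_lon, fixes$lat, fixes$lon)
  fixes[d <= radius_km, , drop = FALSE]
}

#' Drop fixes implying implausible travel speed
#'
#' Optional quality gate (off by default in the pipeline): removes a fix
#' whenever the speed from the previous retained fix exceeds `max_kmh`.
#'
#' @param fixes data.frame with `time` (POSIXct), `lat`, `lon`
#' @param max_kmh speed ceiling, km/h
#' @return retained rows
#' @export
filter_max_speed <- function(fixes, max_kmh = 200) {
  n <- nrow(fixes)
  if (n <= 1L) return(fixes)
  keep <- logical(n); keep[1L] <- TRUE
  last <- 1L
  for (i in 2:n) {
    dt_h <- as.numeric(difftime(fixes$time[i], fixes$time[last], units = "hours"))
    dk <- haversine_km(fixes$lat[last], fixes$lon[last], fixes$lat[i], fixes$lon[i])
    if (dt_h <= 0 || dk / dt_h <= max_kmh) { keep[i] <- TRUE; last <- i }
  }
  fixes[keep, , drop = FALSE]
}

#' Estimate a home location from daily first fixes
#'
#' Fallback when no surveyed home coordinate is available: the medoid of
#' each day's first fix (the fix minimising summed distance to the others).
#' The pipeline treats home as a required input; this estimator is opt-in.
#'
#' @param tracks data.frame of fixes with `date`, `lat`, `lon`
#' @return list with `lat`, `lon`
#' @export
estimate_home <- function(tracks) {
  if (nrow(tracks) == 0L) stop("estimate_home: no fixes", call. = FALSE)
  firsts <- do.call(rbind, lapply(split(tracks, tracks$date), function(d) d[1L, c("lat", "lon")]))
  if (nrow(firsts) == 1L) return(list(lat = firsts$lat, lon = firsts$lon))
  dm <- outer(seq_len(nrow(firsts)), seq_len(nrow(firsts)), function(i, j)
    haversine_km(firsts$lat[i], firsts$lon[i], firsts$lat[j], firsts$lon[j]))
  k <- which.min(rowSums(dm))
  list(lat = firsts$lat[k], lon = firsts$lon[k])
}
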