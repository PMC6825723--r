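# Life-space mobility outcomes from daily GPS fixes.
#
# Three outcomes per participant: mean daily life-space area (convex hull of
# one day's fixes, km^2), mean daily distance (cumulative path length, km),
# and the maximum action range over the whole registration period (largest
# straight-line distance from home, km).  All are computed after the 15-km
# home-radius filter.

#' Shoelace area of the convex hull of planar points (km^2)
#'
#' Hull vertices from [grDevices::chull()]; area by the shoelace formula.
#' Returns 0 for degenerate (collinear) hulls.
#' @param x_km,y_km planar coordinates in km
#' @keywords internal
hull_area_km2 <- function(x_km, y_km) {
  pts <- unique(cbind(x_km, y_km))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(h) < 3L) return(0)
  x <- pts[h, 1L]; y <- pts[h, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Daily life-space area
#'
#' Convex-hull area of one day's fixes, computed on a local
#' azimuthal-equidistant plane centred at home.  Days with fewer than three
#' distinct fixes have no defined hull and return `NA` (not zero), so that
#' GPS-dropout days do not deflate a participant's average; three or more
#' collinear fixes give 0.
#'
#' @param track data.frame of one day's fixes (`lat`, `lon`), already
#'   home-filtered
#' @param home_lat,home_lon home coordinates, degrees
#' @return area in km^2, or `NA_real_` if undefined
#' @export
daily_life_space_area <- function(track, home_lat, home_lon) {
  if (nrow(track) == 0L) return(NA_real_)
  distinct <- unique(track[, c("lat", "lon")])
  if (nrow(distinct) < 3L) return(NA_real_)
  xy <- project_local(distinct$lat, distinct$lon, home_lat, home_lon)
  hull_area_km2(xy$x_km, xy$y_km)
}

#' Daily travelled distance
#'
#' `mode = "path"` (default): cumulative path length, the sum of
#' great-circle distances between consecutive fixes.  `mode = "net"`:
#' straight-line displacement between the first and last fix of the day.
#' Path length is the reading consistent with daily totals in the tens of
#' kilometres for urban cohorts; both are exposed.
#'
#' @param track data.frame of one day's fixes ordered by time
#' @param mode `"path"` or `"net"`
#' @return distance in km (0 for one fix or none)
#' @export
daily_path_distance <- function(track, mode = c("path", "net")) {
  mode <- match.arg(mode)
  n <- nrow(track)
  if (n <= 1L) return(0)
  if (mode == "net")
    return(haversine_km(track$lat[1L], track$lon[1L], track$lat[n], track$lon[n]))
  sum(haversine_km(track$lat[-n], track$lon[-n], track$lat[-1L], track$lon[-1L]))
}

#' Maximum action range over a registration period
#'
#' Largest great-circle distance from home over all of a participant's
#' (home-filtered) fixes; a period-level maximum, not a daily average.
#'
#' @param fixes data.frame of all fixes of one participant (`lat`, `lon`)
#' @param home_lat,home_lon home coordinates, degrees
#' @return km; `NA_real_` when there are no fixes at all
#' @export
action_range_max <- function(fixes, home_lat, home_lon) {
  if (nrow(fixes) == 0L) return(NA_real_)
  max(haversine_km(home_lat, home_lon, fixes$lat, fixes$lon))
}

#' Per-day GPS metrics for one participant
#'
#' Applies the home-radius filter (and optionally the speed gate), then
#' computes the daily area, distance and per-day maximum home distance.
#'
#' @param fixes data.frame with `date`, `time`, `lat`, `lon` for one
#'   participant, ordered by time
#' @param home_lat,home_lon home coordinates
#' @param radius_km home filter radius (default 15)
#' @param distance_mode `"path"` or `"net"`, see [daily_path_distance()]
#' @param max_speed_kmh optional speed gate; `NULL` (default) disables it
#' @return data.frame: `date`, `n_fixes`, `life_space_area_km2`,
#'   `path_distance_km`, `max_home_distance_km`, `valid`
#' @export
gps_day_metrics <- function(fixes, home_lat, home_lon, radius_km = 15,
                            distance_mode = "path", max_speed_kmh = NULL) {
  fixes <- filter_home_radius(fixes, home_lat, home_lon, radius_km)
  if (!is.null(max_speed_kmh)) fixes <- filter_max_speed(fixes, max_speed_kmh)
  days <- split(fixes, as.character(fixes$date))
  rows <- lapply(names(days), function(d) {
    tr <- days[[d]]
    data.frame(
      date = d,
      n_fixes = nrow(tr),
      life_space_area_km2 = daily_life_space_area(tr, home_lat, home_lon),
      path_distance_km = daily_path_distance(tr, distance_mode),
      max_home_distance_km = max(haversine_km(home_lat, home_lon, tr$lat, tr$lon)),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(date = character(), n_fixes = integer(),
               life_space_area_km2 = numeric(), path_distance_km = numeric(),
               max_home_distance_km = numeric())
  out$valid <- out$n_fixes > 0L
  out[order(out$date), , drop = FALSE]
}

#' Participant-level GPS summary
#'
#' Mean daily life-space area and distance over days where they are
#' defined, plus the period maximum action range.
#'
#' @param day_metrics output of [gps_day_metrics()]
#' @return one-row data.frame: `life_space_area`, `distance`, `ar_max`,
#'   `n_days_area`, `n_days_distance`, `usable` (FALSE when no day yields a
#'   defined metric)
#' @export
summarize_gps <- function(day_metrics) {
  area <- day_metrics$life_space_area_km2
  dist <- day_metrics$path_distance_km
  amax <- day_metrics$max_home_distance_km
  n_area <- sum(!is.na(area))
  n_dist <- sum(!is.na(dist))
  data.frame(
    life_space_area = if (n_area) mean(area, na.rm = TRUE) else NA_real_,
    distance = if (n_dist) mean(dist, na.rm = TRUE) else NA_real_,
    ar_max = if (length(amax) && any(!is.na(amax))) max(amax, na.rm = TRUE) else NA_real_,
    n_days_area = n_area,
    n_days_distance = n_dist,
    usable = n_dist > 0L)
}
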