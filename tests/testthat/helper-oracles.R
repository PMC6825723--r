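# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: hull areas by exhaustive extreme-point search, spherical
# polygon areas by l'Huilier triangulation, Spearman by manual mid-ranks
# and the explicit Pearson sum formula, VIF from the inverse correlation
# matrix, quartiles by the hand-written type-7 interpolation rule.

R_SPHERE <- 6371.0088

# O(n^3) convex hull area: a directed pair (i, j) is a hull edge iff every
# other point lies on its left; hull vertices are points on any such edge,
# ordered by angle about their centroid, then shoelace.
brute_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  scale <- max(abs(pts), 1)
  eps <- 1e-12 * scale^2
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ex <- pts[j, 1] - pts[i, 1]; ey <- pts[j, 2] - pts[i, 2]
    cr <- (pts[, 1] - pts[i, 1]) * ey - (pts[, 2] - pts[i, 2]) * ex
    if (all(cr <= eps)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  v <- pts[on_hull, , drop = FALSE]
  if (nrow(v) < 3L) return(0)
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  o <- order(atan2(v[, 2] - cy, v[, 1] - cx))
  v <- v[o, , drop = FALSE]
  xs <- v[, 1]; ys <- v[, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# Spherical (geodesic) polygon area by fan triangulation from the first
# vertex with l'Huilier's spherical-excess formula; vertices must be in
# hull order.
gc_angle <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * asin(sqrt(pmin(1, pmax(0, a))))
}

spherical_polygon_area_km2 <- function(lat, lon) {
  n <- length(lat)
  if (n < 3L) return(0)
  tri_excess <- function(a, b, c) {
    s <- (a + b + c) / 2
    t <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - c) / 2)
    4 * atan(sqrt(max(0, t)))
  }
  total <- 0
  for (k in 2:(n - 1)) {
    a <- gc_angle(lat[1], lon[1], lat[k], lon[k])
    b <- gc_angle(lat[k], lon[k], lat[k + 1], lon[k + 1])
    c <- gc_angle(lat[k + 1], lon[k + 1], lat[1], lon[1])
    total <- total + tri_excess(a, b, c)
  }
  total * R_SPHERE^2
}

# manual mid-ranks + explicit Pearson sum formula
brute_spearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# VIFs as the diagonal of the inverse correlation matrix
brute_vif <- function(X) diag(solve(stats::cor(X)))

# type-7 quartiles by the interpolation rule, then fences
brute_tukey_fences <- function(x, k = 1.5) {
  q7 <- function(p) {
    s <- sort(x); n <- length(s)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75)
  c(q1 - k * (q3 - q1), q3 + k * (q3 - q1))
}

# destination point on the sphere: start, bearing (deg), distance (km)
geodesic_destination <- function(lat, lon, bearing_deg, dist_km) {
  rad <- pi / 180
  d <- dist_km / R_SPHERE
  th <- bearing_deg * rad
  p1 <- lat * rad
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- lon * rad + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  c(lat = p2 / rad, lon = ((l2 / rad + 180) %% 360) - 180)
}

# intervals constructor for activity tests
iv <- function(date, from, to, class, met, steps = 0) {
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  data.frame(start = d0 + from * 3600, end = d0 + to * 3600,
             class = class, met = met, steps = steps, stringsAsFactors = FALSE)
}
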