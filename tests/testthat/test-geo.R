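test_that("haversine matches closed forms and is symmetric", {
  expect_identical(haversine_km(50.5, 6.5, 50.5, 6.5), 0)
  # one degree of latitude at the equator: R * pi/180
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0088 * pi / 180, tolerance = 1e-8)
  # antipodal: pi * R
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -180, 180))
    b <- c(runif(1, -80, 80), runif(1, -180, 180))
    expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                 haversine_km(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_km(95, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 190, 0, 0), "longitude")
})

test_that("local projection preserves range, matches the geodesic oracle, and inverts", {
  home <- c(50.9375, 6.9603)
  # a point 5 km due north
  p <- geodesic_destination(home[1], home[2], 0, 5)
  xy <- project_local(p["lat"], p["lon"], home[1], home[2])
  expect_equal(xy$x_km, 0, tolerance = 1e-6)
  expect_equal(xy$y_km, 5, tolerance = 1e-6)
  expect_equal(unname(unlist(project_local(home[1], home[2], home[1], home[2]))),
               c(0, 0))
  # random bearings/distances: projection radius equals geodesic distance
  set.seed(42)
  brg <- runif(50, 0, 360); dst <- runif(50, 0, 14.9)
  pts <- t(mapply(geodesic_destination, home[1], home[2], brg, dst))
  xy <- project_local(pts[, 1], pts[, 2], home[1], home[2])
  expect_equal(sqrt(xy$x_km^2 + xy$y_km^2), dst, tolerance = 1e-9)
  # round trip within 1e-9 degrees
  back <- unproject_local(xy$x_km, xy$y_km, home[1], home[2])
  expect_equal(back$lat, unname(pts[, 1]), tolerance = 1e-9)
  expect_equal(back$lon, unname(pts[, 2]), tolerance = 1e-9)
  expect_error(project_local(52, 6.96, home[1], home[2]), "filter first")
})

test_that("home-radius filter is inclusive at the boundary and order-preserving", {
  home <- c(50.9375, 6.9603)
  d <- c(0.5, 15, 14.999, 15.001, 20, 1)
  pts <- t(mapply(geodesic_destination, home[1], home[2],
                  c(10, 50, 90, 130, 170, 210), d))
  fixes <- data.frame(id = seq_along(d), lat = pts[, 1], lon = pts[, 2])
  kept <- filter_home_radius(fixes, home[1], home[2], 15)
  expect_equal(kept$id, c(1, 2, 3, 6))   # 15.0 retained, 15.001 and 20 dropped
  near <- fixes[d < 1.5, ]
  expect_identical(filter_home_radius(near, home[1], home[2]), near)
})

test_that("speed gate drops implausible jumps only", {
  t0 <- as.POSIXct("2016-06-06 10:00:00", tz = "UTC")
  fixes <- data.frame(time = t0 + c(0, 60, 120),
                      lat = c(50.9375, 50.9384, 52.0),  # third implies ~7000 km/h
                      lon = c(6.9603, 6.9603, 6.9603))
  expect_equal(nrow(filter_max_speed(fixes, 200)), 2L)
  expect_equal(nrow(filter_max_speed(fixes[1:2, ], 200)), 2L)
})

test_that("home estimator recovers the anchor of constructed tracks", {
  home <- c(50.9375, 6.9603)
  days <- do.call(rbind, lapply(1:4, function(d) {
    tr <- simulate_day_track(home[1], home[2], 2, 4, 10,
                             as.Date("2016-06-06") + d)
    tr$date <- as.character(as.Date("2016-06-06") + d)
    tr
  }))
  est <- estimate_home(days)
  expect_lt(haversine_km(est$lat, est$lon, home[1], home[2]), 0.01)
})
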