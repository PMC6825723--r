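home <- c(lat = 50.9375, lon = 6.9603)

track_at <- function(bearings, dists, date = "2016-06-06") {
  pts <- t(mapply(geodesic_destination, home[1], home[2], bearings, dists))
  data.frame(time = as.POSIXct(paste(date, "10:00:00"), tz = "UTC") +
               60 * seq_along(bearings),
             lat = unname(pts[, 1]), lon = unname(pts[, 2]))
}

test_that("life-space area: degenerate cases and a known square", {
  # two distinct fixes: undefined, not zero
  expect_true(is.na(daily_life_space_area(track_at(c(0, 90), c(1, 2)),
                                          home[1], home[2])))
  # three collinear fixes: zero
  expect_equal(daily_life_space_area(track_at(c(0, 0, 0), c(1, 2, 3)),
                                     home[1], home[2]), 0, tolerance = 1e-9)
  # empty track
  empty <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(0), lon = numeric(0))
  expect_true(is.na(daily_life_space_area(empty, home[1], home[2])))
  # fixes at the corners of a 2 km x 2 km square on the local plane
  sq_pts <- unproject_local(c(-1, 1, 1, -1), c(2, 2, 4, 4), home[1], home[2])
  sq_track <- data.frame(time = as.POSIXct("2016-06-06 10:00:00", tz = "UTC") + 1:4 * 60,
                         lat = sq_pts$lat, lon = sq_pts$lon)
  expect_equal(daily_life_space_area(sq_track, home[1], home[2]), 4,
               tolerance = 0.005)
})

test_that("path distance: segment sums, out-and-back vs action range", {
  expect_equal(daily_path_distance(track_at(0, 3)), 0)       # single fix
  # fixes on a line at 0, 1, 3 km
  tr <- track_at(c(0, 0, 0), c(0.0001, 1, 3))
  expect_equal(daily_path_distance(tr), 3, tolerance = 1e-3)
  # out-and-back 5 km each way: path 10, range 5
  oab <- track_at(c(0, 0, 0), c(0.0001, 5, 0.0001))
  expect_equal(daily_path_distance(oab), 10, tolerance = 1e-3)
  expect_equal(action_range_max(oab, home[1], home[2]), 5, tolerance = 1e-6)
  # net mode measures first-to-last displacement
  expect_equal(daily_path_distance(oab, mode = "net"), 0, tolerance = 1e-3)
})

test_that("action range: maximum over period, filter precedes metric", {
  tr <- track_at(c(10, 80, 200), c(2, 5, 14.9))
  expect_equal(action_range_max(tr, home[1], home[2]), 14.9, tolerance = 1e-6)
  at_home <- data.frame(time = Sys.time() + 1:3, lat = rep(home[1], 3),
                        lon = rep(home[2], 3))
  expect_equal(action_range_max(at_home, home[1], home[2]), 0)
  expect_true(is.na(action_range_max(at_home[0, ], home[1], home[2])))
  # a 16-km fix disappears after filtering
  raw <- track_at(c(0, 45, 90), c(5, 14.9, 16))
  kept <- filter_home_radius(raw, home[1], home[2], 15)
  expect_equal(action_range_max(kept, home[1], home[2]), 14.9, tolerance = 1e-6)
})

test_that("participant summary: mean over defined days, period max, skip-undefined", {
  dm <- data.frame(date = c("d1", "d2", "d3"), n_fixes = c(50, 2, 40),
                   life_space_area_km2 = c(2, NA, 4),
                   path_distance_km = c(10, 1, 20),
                   max_home_distance_km = c(3, 7, 5), valid = TRUE)
  s <- summarize_gps(dm)
  expect_equal(s$life_space_area, 3)
  expect_equal(s$n_days_area, 2L)
  expect_equal(s$distance, mean(c(10, 1, 20)))
  expect_equal(s$ar_max, 7)
  empty <- summarize_gps(dm[0, ])
  expect_false(empty$usable)
})

test_that("filter monotonicity and post-filter bounds hold on random tracks", {
  set.seed(99)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    tr <- track_at(runif(n, 0, 360), runif(n, 0, 25))
    f <- filter_home_radius(tr, home[1], home[2], 15)
    if (nrow(f) >= 3) {
      a_raw <- daily_life_space_area(tr, home[1], home[2])
      a_f <- daily_life_space_area(f, home[1], home[2])
      expect_lte(a_f, a_raw + 1e-12)
      expect_lte(a_f, pi * 225)
      expect_lte(daily_path_distance(f), daily_path_distance(tr) + 1e-12)
      expect_lte(action_range_max(f, home[1], home[2]), 15)
    }
  }
})

test_that("area and range are invariant under a common small translation", {
  set.seed(5)
  tr <- track_at(runif(10, 0, 360), runif(10, 0, 10))
  a0 <- daily_life_space_area(tr, home[1], home[2])
  r0 <- action_range_max(tr, home[1], home[2])
  dlat <- 0.02; dlon <- 0.03
  tr2 <- tr; tr2$lat <- tr$lat + dlat; tr2$lon <- tr$lon + dlon
  a1 <- daily_life_space_area(tr2, home[1] + dlat, home[2] + dlon)
  r1 <- action_range_max(tr2, home[1] + dlat, home[2] + dlon)
  expect_lt(abs(a1 - a0) / a0, 0.001)
  expect_lt(abs(r1 - r0) / r0, 0.001)
})
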