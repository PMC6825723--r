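D <- "2016-06-06"

test_that("window clipping: proportional, dropping, idempotent", {
  # 06:30-07:30 bout: half retained, steps halved
  cl <- clip_to_window(iv(D, 6.5, 7.5, "gait", 4, steps = 1000))
  expect_equal(registration_hours(cl), 0.5)
  expect_equal(cl$steps, 500)
  # fully outside dropped; fully inside untouched
  expect_equal(nrow(clip_to_window(iv(D, 22, 23, "other", 1.5))), 0L)
  inside <- iv(D, 8, 9, "active", 3.5, steps = 800)
  expect_equal(clip_to_window(inside), inside)
  # idempotence
  mixed <- rbind(iv(D, 6, 8, "gait", 4, 1200), iv(D, 8, 9, "other", 1.5),
                 iv(D, 20.5, 21.5, "active", 3.2, 400))
  once <- clip_to_window(mixed)
  expect_equal(clip_to_window(once), once)
})

test_that("registration hours sum interval coverage across classes", {
  full <- iv(D, 7, 21, "other", 1.5)
  expect_equal(registration_hours(clip_to_window(full)), 14)
  two <- rbind(iv(D, 8, 10, "gait", 4), iv(D, 12, 14, "other", 1))
  expect_equal(registration_hours(two), 4)
  expect_equal(registration_hours(two[0, ]), 0)
})

test_that("day validity boundary is inclusive at 9 h", {
  expect_false(is_valid_day(8.9))
  expect_true(is_valid_day(9.0))
  expect_true(is_valid_day(14))
})

test_that("AGT counts only gait/active bouts strictly above 3 METs", {
  ivs <- rbind(iv(D, 8.0, 8.5, "gait", 3.5),    # counts (0.5 h)
               iv(D, 9.0, 9.333333, "active", 2.5),  # too light
               iv(D, 10, 11, "gait", 4.0))      # counts (1 h)
  expect_equal(daily_agt(ivs), 1.5, tolerance = 1e-6)
  # exactly 3.0 METs contributes nothing
  expect_equal(daily_agt(iv(D, 8, 10, "gait", 3.0)), 0)
  # "other" never counts regardless of intensity
  expect_equal(daily_agt(iv(D, 8, 10, "other", 5.0)), 0)
  expect_equal(daily_agt(ivs[0, ]), 0)
})

test_that("steps sum over retained intervals", {
  ivs <- rbind(iv(D, 8, 9, "gait", 4, 3000), iv(D, 9, 10, "other", 1.5, 0),
               iv(D, 10, 11, "active", 3.5, 7000))
  expect_equal(daily_steps(ivs), 10000)
  expect_equal(daily_steps(ivs[0, ]), 0)
})

test_that("12-h scaling formula and identity", {
  expect_equal(scale_to_12h(0.9, 10.8), 1.0)
  expect_equal(scale_to_12h(3.7, 12), 3.7)
  expect_equal(scale_to_12h(5000, 9.6), 6250)
  expect_error(scale_to_12h(1, 0), "registration hours")
})

test_that("participant summary averages scaled values over valid days only", {
  dm <- data.frame(date = c("d1", "d2", "d3"),
                   registration_h = c(10, 12, 8),
                   agt_raw_h = c(1, 2, 1), agt_scaled_h = c(1.0, 2.0, NA),
                   steps_raw = c(5000, 8000, 100),
                   steps_scaled = c(6000, 8000, NA),
                   valid = c(TRUE, TRUE, FALSE))
  s <- summarize_activity(dm)
  expect_equal(s$agt, 1.5)
  expect_equal(s$steps, 7000)
  expect_equal(s$n_valid_days, 2L)
  # idempotence over identical days
  same <- dm[c(2, 2, 2), ]
  expect_equal(summarize_activity(same)$agt, 2.0)
  expect_false(summarize_activity(dm[FALSE, ])$usable)
})

test_that("day metrics pipeline: conservation and scaling direction", {
  set.seed(8)
  for (i in 1:10) {
    reg <- runif(1, 9, 14)
    agt <- runif(1, 0, reg / 3)
    ivs <- simulate_activity_day(agt, round(runif(1, 0, 15000)), D, reg_hours = 12)
    ivs$date <- D
    dm <- activity_day_metrics(ivs)
    expect_lte(dm$agt_raw_h, dm$registration_h)
    # 12-h registration: scaled == raw
    expect_equal(dm$agt_scaled_h, dm$agt_raw_h)
    expect_equal(dm$steps_scaled, dm$steps_raw)
  }
})
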