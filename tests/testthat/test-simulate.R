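iid_spec <- function(k) data.frame(name = paste0("v", seq_len(k)),
                                   domain = "x", mean = 0, sd = 1)
iid_corr <- function(k) {
  P <- diag(k); dimnames(P) <- list(paste0("v", 1:k), paste0("v", 1:k)); P
}

test_that("covariate simulation: determinism, empty case, correlation recovery", {
  cfg <- simulation_config(n_participants = 30, seed = 7)
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  cfg0 <- simulation_config(n_participants = 0)
  expect_equal(nrow(simulate_covariates(cfg0)), 0L)
  # corr(grip, leg) = 0.45 by default: recovered within +-0.05 at n = 10000
  big <- simulation_config(n_participants = 10000, seed = 8)
  cv <- simulate_covariates(big)
  expect_equal(cor(cv$grip_strength, cv$leg_strength), 0.45, tolerance = 0.05 / 0.45)
  expect_equal(mean(cv$age), 71, tolerance = 0.01)
  expect_equal(sd(cv$grip_strength), 113, tolerance = 0.05)
  # non-PD correlation spec rejected
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3,
                dimnames = list(c("v1", "v2", "v3"), c("v1", "v2", "v3")))
  expect_error(simulation_config(covariate_spec = iid_spec(3), correlations = bad,
                                 std_effects = list(), effect_spec = list()),
               "positive definite")
})

test_that("mobility targets: degenerate model, clipping, coefficient recovery", {
  # all betas 0, noise 0: everyone identical
  cfg <- simulation_config(n_participants = 20, covariate_spec = iid_spec(2),
                           correlations = iid_corr(2), std_effects = list(),
                           effect_spec = list(agt = numeric(0)),
                           intercepts = c(agt = 1.2), noise_sd = c(agt = 0))
  t0 <- simulate_mobility_targets(simulate_covariates(cfg), cfg)
  expect_equal(t0$targets$agt, rep(1.2^2, 20))
  # negative linear predictor clips to 0
  cfgn <- simulation_config(n_participants = 10, covariate_spec = iid_spec(2),
                            correlations = iid_corr(2), std_effects = list(),
                            effect_spec = list(agt = numeric(0)),
                            intercepts = c(agt = -3), noise_sd = c(agt = 0))
  tn <- simulate_mobility_targets(simulate_covariates(cfgn), cfgn)
  expect_equal(tn$targets$agt, rep(0, 10))
  # unknown covariate in effect_spec rejected
  expect_error(simulation_config(covariate_spec = iid_spec(2),
                                 correlations = iid_corr(2), std_effects = list(),
                                 effect_spec = list(agt = c(zz = 0.5))),
               "unknown covariate")
  # beta = 0.5, noise 0.1, n = 1000: OLS on the z-scored covariate recovers 0.5
  cfg5 <- simulation_config(n_participants = 1000, covariate_spec = iid_spec(1),
                            correlations = iid_corr(1), std_effects = list(),
                            effect_spec = list(agt = c(v1 = 0.5)),
                            intercepts = c(agt = 5), noise_sd = c(agt = 0.1),
                            seed = 9)
  cv <- simulate_covariates(cfg5)
  tt <- simulate_mobility_targets(cv, cfg5)
  fit <- lm(sqrt(tt$targets$agt) ~ scale(cv$v1))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.03 / 0.5)
  # ar_max never exceeds 15
  cfga <- simulation_config(n_participants = 200, seed = 10)
  ta <- simulate_mobility_targets(simulate_covariates(cfga), cfga)
  expect_lte(max(ta$targets$ar_max), 15)
  expect_gte(min(ta$targets$ar_max), 0)
})

test_that("constructed day tracks realize their targets", {
  h <- c(50.9375, 6.9603)
  tr <- simulate_day_track(h[1], h[2], 0, 5, 10, "2016-06-06")
  expect_equal(action_range_max(tr, h[1], h[2]), 5, tolerance = 1e-6)
  # stay-at-home day
  tr0 <- simulate_day_track(h[1], h[2], 0, 0, 0, "2016-06-06")
  expect_equal(daily_path_distance(tr0), 0)
  expect_equal(action_range_max(tr0, h[1], h[2]), 0)
  expect_true(is.na(daily_life_space_area(tr0, h[1], h[2])) ||
                daily_life_space_area(tr0, h[1], h[2]) == 0)
  # area target realized within 10%
  tr4 <- simulate_day_track(h[1], h[2], 4, 6, 25, "2016-06-06")
  expect_equal(daily_life_space_area(tr4, h[1], h[2]), 4, tolerance = 0.1)
  expect_equal(daily_path_distance(tr4), 25, tolerance = 0.01)
  # >= 3 non-collinear fixes whenever area target > 0
  expect_gt(daily_life_space_area(tr4, h[1], h[2]), 0)
  # timestamps strictly increasing, inside 07:00-21:00
  expect_true(all(diff(as.numeric(tr4$time)) > 0))
  hrs <- as.numeric(format(tr4$time, "%H"))
  expect_true(all(hrs >= 7 & hrs < 21))
  expect_error(simulate_day_track(h[1], h[2], 1, 16, 40, "2016-06-06"), "15")
  # exceptional trip plants a fix beyond the filter radius
  tre <- simulate_day_track(h[1], h[2], 2, 5, 15, "2016-06-06",
                            exceptional_trip = TRUE)
  expect_gt(action_range_max(tre, h[1], h[2]), 15)
  # filtering removes the beyond-15-km fixes (en-route fixes may remain)
  expect_lte(action_range_max(filter_home_radius(tre, h[1], h[2]), h[1], h[2]), 15)
})

test_that("constructed activity days realize their targets exactly", {
  ivs <- simulate_activity_day(1.5, 10000, "2016-06-06")
  cl <- clip_to_window(ivs)
  expect_equal(daily_agt(cl), 1.5)
  expect_equal(daily_steps(cl), 10000)
  expect_equal(registration_hours(cl), 12)
  # AGT target 0: no bout exceeds 3 METs, steps still present
  z <- simulate_activity_day(0, 4000, "2016-06-06")
  expect_true(all(z$met <= 3))
  expect_equal(daily_steps(clip_to_window(z)), 4000)
  expect_equal(daily_agt(clip_to_window(z)), 0)
  expect_error(simulate_activity_day(13, 0, "2016-06-06", reg_hours = 12),
               "does not fit")
  expect_error(simulate_activity_day(-1, 0, "2016-06-06"), "negative")
})

test_that("missingness injection: identity, concentration, independence, MAR", {
  df <- as.data.frame(matrix(rnorm(10000), 1000, 10))
  out0 <- inject_missingness(df, 0, seed = 1)
  expect_identical(as.data.frame(out0)[names(df)], df)
  out <- inject_missingness(df, 0.03, "mcar", seed = 2)
  frac <- mean(is.na(as.matrix(out[names(df)])))
  expect_gte(frac, 0.02); expect_lte(frac, 0.04)
  # MCAR mask is independent of cell values (point-biserial ~ 0)
  m <- attr(out, "miss_mask")
  pb <- cor(as.numeric(m[, 1]), df[[1]])
  expect_lt(abs(pb), 0.08)
  expect_error(inject_missingness(df, 1), "rate")
  # MAR: missingness of other columns depends on the driver
  outm <- inject_missingness(df, 0.1, "mar", seed = 3)
  mm <- attr(outm, "miss_mask")
  expect_true(all(!mm[, 1]))                    # driver never masked
  r <- cor(df[[1]], rowMeans(mm[, -1]))
  expect_gt(r, 0.2)
})

test_that("study bundle generation: counts, determinism, day range", {
  cfg <- simulation_config(n_participants = 12, seed = 77, day_sdlog = 0.2)
  d1 <- file.path(tempdir(), "stA"); d2 <- file.path(tempdir(), "stB")
  generate_study(cfg, d1); generate_study(cfg, d2)
  part <- read.csv(file.path(d1, "participants.csv"))
  expect_equal(nrow(part), 12L)
  gfiles <- list.files(file.path(d1, "gps"))
  afiles <- list.files(file.path(d1, "activity"))
  expect_equal(length(gfiles), length(afiles))
  per <- table(sub("_.*", "", gfiles))
  expect_true(all(per >= 6 & per <= 9))
  # byte-identical truth across runs with the same seed
  expect_identical(readBin(file.path(d1, "truth.json"), "raw", 1e6),
                   readBin(file.path(d2, "truth.json"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "participants.csv"), "raw", 1e6),
                   readBin(file.path(d2, "participants.csv"), "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
})
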