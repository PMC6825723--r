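# Synthetic study generator.  Emulates the statistical structure the
# analysis chain assumes -- a cohort of older adults monitored ~7 days,
# home-anchored daily GPS trajectories, classified activity bouts,
# multi-domain covariates with a stated correlation structure, a linear
# effect of a covariate subset on square-root-scale mobility outcomes,
# MCAR missingness and injected outliers -- with full ground truth, so
# every downstream stage is testable without any real data.
#
# Fidelity is to the statistical structure only: trips are out-and-back
# radial polylines, not realistic human trajectories.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default multi-domain covariate roster
#'
#' Twelve variables spanning the demographic, environmental, physical,
#' cognitive, psychological and social domains of a typical
#' community-dwelling-older-adult test battery, with means/SDs on the
#' scales such instruments report (grip strength in N, leg strength in
#' kg/kg body weight, gait speed in m/s, daily maximum temperature in
#' degrees C, questionnaire scores in points). Gender and education are
#' numeric codes, matching how such tables enter rank correlations.
#'
#' @return data.frame: `name`, `domain`, `mean`, `sd`
#' @export
default_covariate_spec <- function() {
  data.frame(
    name = c("age", "gender", "education", "max_temperature",
             "grip_strength", "leg_strength", "gait_speed",
             "hotap_a", "attention_window",
             "fes", "mpte3", "isel_tss"),
    domain = c("demographic", "demographic", "demographic", "environmental",
               "physical", "physical", "physical",
               "cognitive", "cognitive",
               "psychological", "social", "social"),
    mean = c(71.0, 0.62, 0.22, 21.5, 282, 1.45, 1.38, 11.6, 52, 19.3, 2.5, 20.6),
    sd   = c(5.6, 0.49, 0.42, 3.7, 113, 0.45, 0.15, 4.6, 25, 4.2, 2.1, 3.6),
    stringsAsFactors = FALSE)
}

#' Default covariate correlation matrix
#'
#' Modest, positive-definite structure: the strength/gait measures
#' correlate with each other and decline with age; fall-related efficacy
#' tracks physical function; the two social scores correlate; women have
#' lower grip strength.
#'
#' @param names covariate names (default: the default roster)
#' @return correlation matrix
#' @export
default_covariate_correlations <- function(names = default_covariate_spec()$name) {
  p <- length(names)
  P <- diag(p); dimnames(P) <- list(names, names)
  set_r <- function(a, b, r) {
    if (a %in% names && b %in% names) { P[a, b] <<- r; P[b, a] <<- r }
  }
  set_r("grip_strength", "leg_strength", 0.45)
  set_r("grip_strength", "gait_speed", 0.25)
  set_r("leg_strength", "gait_speed", 0.30)
  set_r("age", "grip_strength", -0.30)
  set_r("age", "leg_strength", -0.30)
  set_r("age", "gait_speed", -0.35)
  set_r("age", "attention_window", -0.25)
  set_r("age", "hotap_a", -0.20)
  set_r("fes", "gait_speed", -0.25)
  set_r("fes", "leg_strength", -0.20)
  set_r("hotap_a", "attention_window", 0.30)
  set_r("mpte3", "isel_tss", 0.20)
  set_r("gender", "grip_strength", -0.45)
  P
}

# Outcome scales: natural-scale mean/SD of the five mobility outcomes in a
# non-mobility-limited urban cohort, and the standardized effects of the
# default covariates on each (sqrt scale).  Distance has no canonical
# published effect structure (it differed between recruitment waves in the
# motivating cohort), so its defaults are package-chosen.
outcome_scales <- function() {
  data.frame(
    outcome = c("agt", "steps", "life_space_area", "distance", "ar_max"),
    mean = c(1.10, 9900, 12.5, 30, 9.55),
    sd   = c(0.51, 3500, 15, 22, 4.6),
    stringsAsFactors = FALSE)
}

default_std_effects <- function() {
  list(
    agt = c(age = -0.287, leg_strength = 0.201),
    steps = c(leg_strength = 0.232),
    life_space_area = c(grip_strength = 0.297, age = -0.198),
    distance = c(leg_strength = 0.20, age = -0.20),
    ar_max = c(grip_strength = 0.244))
}

#' Build a simulation configuration
#'
#' The defaults are the stated world of the package: ~150 participants,
#' 6-9 registration days (most often 7), a Cologne-like home region, the
#' default 12-covariate roster and correlation structure, standardized
#' effects on square-root-scale outcomes with noise calibrated so the
#' true model R-squared is low-to-moderate, ~3% MCAR missingness and
#' ~0.9% injected outliers.
#'
#' `effect_spec` entries are coefficients of the z-scored covariate on
#' the square-root outcome scale; if `NULL` they are derived from
#' standardized effect sizes (`std_effects`) and the outcome scales.
#'
#' @param n_participants cohort size (default 150)
#' @param days_range,days_prob support and probabilities of the per-
#'   participant number of registration days (default 6:9 with mass on 7)
#' @param home_lat,home_lon,home_radius_km home-region disc
#' @param covariate_spec data.frame name/domain/mean/sd
#' @param correlations covariate correlation matrix (positive definite)
#' @param std_effects named list: outcome -> named vector of standardized
#'   betas
#' @param effect_spec optional explicit sqrt-scale coefficients
#'   (overrides `std_effects`)
#' @param intercepts,noise_sd optional named vectors on the sqrt scale;
#'   derived from the outcome scales when `NULL`
#' @param missing_rate covariate cell missingness fraction in [0, 1)
#' @param missing_mechanism `"mcar"`, `"mar"` or `"mnar"`
#' @param outlier_rate fraction of covariate cells turned into gross
#'   outliers, in [0, 1)
#' @param day_sdlog log-scale SD of the lognormal day-level multiplier on
#'   outcome targets (mean-1 multipliers; 0 disables day variability)
#' @param reg_hours daily activity registration hours in [9, 14]
#' @param fix_spacing_km GPS fix spacing along simulated legs
#' @param exceptional_trip_rate fraction of participant-days given an
#'   extra trip beyond the 15-km filter radius (tests the filter)
#' @param seed master seed
#' @return list of class `mobiscope_simconfig`
#' @export
simulation_config <- function(n_participants = 150,
                              days_range = 6:9,
                              days_prob = c(0.08, 0.83, 0.05, 0.04),
                              home_lat = 50.9375, home_lon = 6.9603,
                              home_radius_km = 8,
                              covariate_spec = default_covariate_spec(),
                              correlations = NULL,
                              std_effects = default_std_effects(),
                              effect_spec = NULL,
                              intercepts = NULL,
                              noise_sd = NULL,
                              missing_rate = 0.03,
                              missing_mechanism = c("mcar", "mar", "mnar"),
                              outlier_rate = 0.0088,
                              day_sdlog = 0.25,
                              reg_hours = 12,
                              fix_spacing_km = 0.25,
                              exceptional_trip_rate = 0,
                              seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_participants >= 0, all(days_range %in% 6:9),
            length(days_prob) == length(days_range),
            missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1,
            all(covariate_spec$sd > 0),
            reg_hours >= 9, reg_hours <= 14, day_sdlog >= 0)
  if (is.null(correlations))
    correlations <- default_covariate_correlations(covariate_spec$name)
  correlations <- correlations[covariate_spec$name, covariate_spec$name,
                               drop = FALSE]
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("simulation_config: covariate correlation matrix is not positive definite",
         call. = FALSE)

  sc <- outcome_scales()
  sd_sqrt <- sc$sd / (2 * sqrt(sc$mean))       # delta method
  names(sd_sqrt) <- sc$outcome
  if (is.null(intercepts))
    intercepts <- stats::setNames(sqrt(sc$mean), sc$outcome)
  if (is.null(effect_spec)) {
    effect_spec <- lapply(stats::setNames(sc$outcome, sc$outcome), function(oc) {
      b <- std_effects[[oc]]
      if (is.null(b)) numeric(0) else b * sd_sqrt[[oc]]
    })
  }
  for (oc in names(effect_spec)) {
    unknown <- setdiff(names(effect_spec[[oc]]), covariate_spec$name)
    if (length(unknown))
      stop("simulation_config: effect_spec for '", oc,
           "' references unknown covariate(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  if (is.null(noise_sd)) {
    noise_sd <- vapply(sc$outcome, function(oc) {
      b <- effect_spec[[oc]]
      expl <- if (length(b)) {
        P <- correlations[names(b), names(b), drop = FALSE]
        drop(t(b) %*% P %*% b)
      } else 0
      sqrt(max(sd_sqrt[[oc]]^2 - expl, 1e-6))
    }, numeric(1))
    names(noise_sd) <- sc$outcome
  }
  structure(list(n_participants = n_participants, days_range = days_range,
                 days_prob = days_prob / sum(days_prob),
                 home_lat = home_lat, home_lon = home_lon,
                 home_radius_km = home_radius_km,
                 covariate_spec = covariate_spec, correlations = correlations,
                 effect_spec = effect_spec, intercepts = intercepts,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 outlier_rate = outlier_rate, day_sdlog = day_sdlog,
                 reg_hours = reg_hours, fix_spacing_km = fix_spacing_km,
                 exceptional_trip_rate = exceptional_trip_rate,
                 seed = as.integer(seed)),
            class = "mobiscope_simconfig")
}

#' Draw the covariate table
#'
#' Multivariate-normal draws honouring the configured means, SDs and
#' correlations. Deterministic for a fixed seed.
#'
#' @param config a [simulation_config()]
#' @param seed override of `config$seed` (optional)
#' @return data.frame `participant_id` + one column per covariate; the
#'   z-scores used for effect generation are attached as attribute `"z"`
#' @export
simulate_covariates <- function(config, seed = config$seed) {
  spec <- config$covariate_spec
  n <- config$n_participants
  p <- nrow(spec)
  Z <- with_seed(seed, {
    U <- matrix(stats::rnorm(n * p), n, p)
    U %*% chol(config$correlations)
  })
  colnames(Z) <- spec$name
  X <- sweep(sweep(Z, 2L, spec$sd, `*`), 2L, spec$mean, `+`)
  out <- data.frame(participant_id = sprintf("P%03d", seq_len(n) - 1L + 1L),
                    X, stringsAsFactors = FALSE)
  if (n == 0L) out <- data.frame(participant_id = character(0),
                                 matrix(numeric(0), 0, p,
                                        dimnames = list(NULL, spec$name)))
  attr(out, "z") <- Z
  out
}

#' Latent mobility targets from the covariates
#'
#' For each outcome, `sqrt(target) = intercept + sum_k beta_k z_k +
#' noise`, truncated at zero before squaring; AR-max targets are
#' additionally capped at 15 km so the home-radius filter is non-binding
#' on clean data.
#'
#' @param covariates output of [simulate_covariates()]
#' @param config a [simulation_config()]
#' @param seed override of `config$seed + 1` (optional)
#' @return list of class `mobiscope_truth`: `targets` (data.frame of
#'   participant_id + one column per outcome), `effects` (raw sqrt-scale
#'   coefficients), `std_betas` (implied standardized betas),
#'   `intercepts`, `noise_sd`, `mechanism`
#' @export
simulate_mobility_targets <- function(covariates, config, seed = config$seed + 1L) {
  spec <- config$covariate_spec
  n <- nrow(covariates)
  Z <- attr(covariates, "z")
  if (is.null(Z)) {           # covariates supplied externally: z-score by spec
    Z <- sweep(sweep(as.matrix(covariates[, spec$name, drop = FALSE]),
                     2L, spec$mean), 2L, spec$sd, `/`)
  }
  outcomes <- names(config$effect_spec)
  targets <- data.frame(participant_id = covariates$participant_id,
                        stringsAsFactors = FALSE)
  std_betas <- list()
  with_seed(seed, {
    for (oc in outcomes) {
      b <- config$effect_spec[[oc]]
      lin <- rep(config$intercepts[[oc]], n)
      if (length(b)) lin <- lin + drop(Z[, names(b), drop = FALSE] %*% b)
      s <- lin + stats::rnorm(n, 0, config$noise_sd[[oc]])
      val <- pmax(0, s)^2
      if (oc == "ar_max") val <- pmin(val, 15)
      targets[[oc]] <- val
      expl <- if (length(b)) {
        P <- config$correlations[names(b), names(b), drop = FALSE]
        drop(t(b) %*% P %*% b)
      } else 0
      sdy <- sqrt(expl + config$noise_sd[[oc]]^2)
      std_betas[[oc]] <- if (length(b)) b / sdy else numeric(0)
    }
  })
  structure(list(targets = targets, effects = config$effect_spec,
                 std_betas = std_betas, intercepts = config$intercepts,
                 noise_sd = config$noise_sd,
                 mechanism = config$missing_mechanism),
            class = "mobiscope_truth")
}

#' Construct one day's GPS track hitting stated targets
#'
#' Builds home-anchored out-and-back radial trips on the local plane and
#' unprojects them: the farthest waypoint sits at exactly the AR-max
#' target; a perpendicular trip makes the convex hull a triangle of
#' exactly the area target (clipped to the feasible `ar^2/2`); extra
#' radial trips pad the path length to the distance target. Radial legs
#' are geodesics, so recomputed haversine path length matches the planned
#' distance. Fixes are spaced ~1 simulated minute apart between 07:00 and
#' 21:00.
#'
#' @param home_lat,home_lon home coordinates
#' @param area_km2,ar_km,distance_km day targets (`ar_km` in [0, 15])
#' @param date calendar date
#' @param fix_spacing_km nominal spacing of fixes along legs
#' @param exceptional_trip add an extra out-and-back to 16.5 km (beyond
#'   the 15-km filter), to exercise the home-radius filter
#' @return data.frame of fixes: `time` (POSIXct), `lat`, `lon`; realized
#'   targets (after feasibility clipping) attached as attribute
#'   `"realized"` = list(area, ar, distance)
#' @export
simulate_day_track <- function(home_lat, home_lon, area_km2, ar_km,
                               distance_km, date,
                               fix_spacing_km = 0.25,
                               exceptional_trip = FALSE) {
  if (ar_km < 0 || ar_km > 15)
    stop("simulate_day_track: ar_km must be in [0, 15]", call. = FALSE)
  day0 <- as.POSIXct(paste0(as.character(date), " 08:00:00"), tz = "UTC")

  if (ar_km < 1e-9) {                       # stay-at-home day
    k <- 5L
    out <- data.frame(time = day0 + 60 * seq_len(k),
                      lat = rep(home_lat, k), lon = rep(home_lon, k))
    attr(out, "realized") <- list(area = 0, ar = 0, distance = 0)
    return(out)
  }

  area <- max(0, min(area_km2, 0.999 * ar_km^2 / 2))
  waypoints <- list(c(0, ar_km))
  xB <- 0
  if (area > 0) {
    xB <- 2 * area / ar_km
    waypoints <- c(waypoints, list(c(xB, 0)))
  }
  base <- 2 * ar_km + 2 * xB
  rem <- max(0, distance_km - base)
  extra <- 0
  while (rem > 2e-3) {
    r <- min(ar_km, rem / 2)
    waypoints <- c(waypoints, list(c(0, r)))
    extra <- extra + 2 * r
    rem <- rem - 2 * r
  }
  if (exceptional_trip) waypoints <- c(waypoints, list(c(-16.5, 0)))

  total_len <- sum(vapply(waypoints, function(w) 2 * sqrt(sum(w^2)), numeric(1)))
  spacing <- max(fix_spacing_km, total_len / 700)   # keep the day <= ~12 h of fixes

  pts <- list(c(0, 0))
  for (w in waypoints) {
    len <- sqrt(sum(w^2))
    k <- max(1L, ceiling(len / spacing))
    fr <- seq_len(k) / k
    leg_out <- cbind(w[1L] * fr, w[2L] * fr)
    fr_back <- rev(seq_len(k) - 1L) / k
    leg_back <- cbind(w[1L] * fr_back, w[2L] * fr_back)
    pts <- c(pts, list(leg_out), list(leg_back))
  }
  xy <- do.call(rbind, pts)
  ll <- unproject_local(xy[, 1L], xy[, 2L], home_lat, home_lon)
  out <- data.frame(time = day0 + 60 * (seq_len(nrow(ll)) - 1L),
                    lat = ll$lat, lon = ll$lon)
  attr(out, "realized") <- list(area = area, ar = ar_km,
                                distance = base + extra)
  out
}

#' Construct one day's activity intervals hitting stated targets
#'
#' Lays abutting bouts inside the 07:00-21:00 window, centred, covering
#' exactly `reg_hours` of registration: the >3-MET gait and active bouts
#' sum to exactly the AGT target and carry exactly the step target;
#' <=3-MET "other" filler completes the registration time. A zero-AGT day
#' with steps puts them in a low-intensity gait bout (no bout exceeds
#' 3 METs).
#'
#' @param agt_h day AGT target in hours (must fit: <= min(reg_hours, 14))
#' @param steps day step-count target (integer)
#' @param date calendar date
#' @param reg_hours registration hours in [9, 14]
#' @return data.frame of intervals: `start`, `end`, `class`, `met`, `steps`
#' @export
simulate_activity_day <- function(agt_h, steps, date, reg_hours = 12) {
  if (agt_h < 0 || steps < 0) stop("simulate_activity_day: negative target", call. = FALSE)
  if (reg_hours < 9 || reg_hours > 14)
    stop("simulate_activity_day: reg_hours must be in [9, 14]", call. = FALSE)
  if (agt_h > reg_hours)
    stop("simulate_activity_day: AGT target ", agt_h,
         " h does not fit in ", reg_hours, " registration hours", call. = FALSE)
  day0 <- as.POSIXct(paste0(as.character(date), " 00:00:00"), tz = "UTC")
  start <- day0 + 7 * 3600 + round((14 - reg_hours) * 3600 / 2)   # centred, whole s

  # Bout durations in whole seconds so that the CSV timestamp dialect
  # (1-second resolution) round-trips losslessly; the gait/active split is
  # adjusted so the >3-MET seconds sum to exactly the (second-quantized)
  # AGT target.
  reg_s <- round(reg_hours * 3600)
  agt_s <- round(agt_h * 3600)
  if (agt_s > reg_s) agt_s <- reg_s
  if (agt_s > 0) {
    s1 <- round(0.6 * steps); s2 <- steps - s1
    g1 <- round(0.6 * agt_s); g2 <- agt_s - g1
    f1 <- (reg_s - agt_s) %/% 3
    f3 <- reg_s - agt_s - 2 * f1
    bouts <- list(list(f1, "other", 1.5, 0),
                  list(g1, "gait", 4.2, s1),
                  list(f1, "other", 1.5, 0),
                  list(g2, "active", 3.6, s2),
                  list(f3, "other", 1.5, 0))
  } else if (steps > 0) {
    walk <- min(7200, reg_s %/% 4)
    f1 <- (reg_s - walk) %/% 2
    bouts <- list(list(f1, "other", 1.5, 0),
                  list(walk, "gait", 2.5, steps),
                  list(reg_s - walk - f1, "other", 1.5, 0))
  } else {
    bouts <- list(list(reg_s, "other", 1.5, 0))
  }
  cur <- start
  rows <- lapply(bouts, function(b) {
    s <- cur; e <- cur + b[[1L]]
    cur <<- e
    data.frame(start = s, end = e, class = b[[2L]], met = b[[3L]],
               steps = b[[4L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[as.numeric(out$end) > as.numeric(out$start), , drop = FALSE]
}

#' Inject missingness into a covariate table
#'
#' `"mcar"`: each eligible cell is masked independently with probability
#' `rate`. `"mar"`: the masking probability of a cell depends on the
#' participant's value of an always-observed driver column (logistic
#' shift, slope 1.5 per SD). `"mnar"`: cells in the top decile of their
#' own column are masked with probability 0.5 (others with `rate`).
#' Identifier and outcome columns are never masked. The mask is attached
#' as attribute `"miss_mask"`.
#'
#' @param table data.frame
#' @param rate masking probability in [0, 1)
#' @param mechanism `"mcar"` (default), `"mar"` or `"mnar"`
#' @param columns columns eligible for masking (default: numeric columns)
#' @param driver driver column for `"mar"` (default: first eligible
#'   column, which is then itself exempt from masking)
#' @param seed optional seed
#' @return the masked table
#' @export
inject_missingness <- function(table, rate, mechanism = c("mcar", "mar", "mnar"),
                               columns = NULL, driver = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1)
    stop("inject_missingness: rate must be in [0, 1)", call. = FALSE)
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  mask <- matrix(FALSE, nrow(table), length(columns),
                 dimnames = list(NULL, columns))
  if (rate == 0 && mechanism == "mcar") {
    attr(table, "miss_mask") <- mask
    return(table)
  }
  n <- nrow(table)
  with_seed(seed, {
    if (mechanism == "mar") {
      if (is.null(driver)) driver <- columns[1L]
      columns_eff <- setdiff(columns, driver)
      zd <- as.numeric(scale(table[[driver]]))
      pr <- stats::plogis(stats::qlogis(max(rate, 1e-6)) + 1.5 * zd)
      for (cn in columns_eff) mask[, cn] <- stats::runif(n) < pr
    } else if (mechanism == "mnar") {
      for (cn in columns) {
        x <- table[[cn]]
        top <- !is.na(x) & x >= stats::quantile(x, 0.9, na.rm = TRUE)
        pr <- ifelse(top, 0.5, rate)
        mask[, cn] <- stats::runif(n) < pr
      }
    } else {
      for (cn in columns) mask[, cn] <- stats::runif(n) < rate
    }
  })
  for (cn in columns) table[[cn]][mask[, cn]] <- NA
  attr(table, "miss_mask") <- mask
  table
}

#' Inject gross outliers into covariate cells
#'
#' Chosen cells are displaced by eight column-SDs, far outside any Tukey
#' fence; positions recorded in attribute `"outlier_mask"`.
#'
#' @param table data.frame
#' @param rate fraction of cells in [0, 1)
#' @param columns eligible columns (default numeric)
#' @param seed optional seed
#' @return the contaminated table
#' @export
inject_outliers <- function(table, rate, columns = NULL, seed = NULL) {
  if (rate < 0 || rate >= 1)
    stop("inject_outliers: rate must be in [0, 1)", call. = FALSE)
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  mask <- matrix(FALSE, nrow(table), length(columns),
                 dimnames = list(NULL, columns))
  n <- nrow(table)
  if (rate > 0 && n > 0) with_seed(seed, {
    for (cn in columns) {
      hit <- stats::runif(n) < rate & !is.na(table[[cn]])
      if (any(hit)) {
        s <- stats::sd(table[[cn]], na.rm = TRUE)
        table[[cn]][hit] <- table[[cn]][hit] +
          sample(c(-8, 8), sum(hit), replace = TRUE) * s
      }
      mask[, cn] <- hit
    }
  })
  attr(table, "outlier_mask") <- mask
  table
}

#' Generate a complete on-disk synthetic study bundle
#'
#' Writes `participants.csv` (id, home coordinates, covariates with
#' missingness and outliers injected), per-day GPS CSVs under `gps/`,
#' per-day activity CSVs under `activity/`, and `truth.json` holding the
#' latent targets, realized per-day targets, true standardized betas and
#' injection masks. Re-running with the same config yields byte-identical
#' output.
#'
#' @param config a [simulation_config()]
#' @param out_dir output directory (created if needed)
#' @return the bundle path, invisibly; the truth object as attribute
#' @export
generate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("generate_study: cannot create '", out_dir, "'", call. = FALSE)
  dir.create(file.path(out_dir, "gps"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "activity"), showWarnings = FALSE)

  cov <- simulate_covariates(config)
  truth <- simulate_mobility_targets(cov, config)
  n <- nrow(cov)

  # home locations: uniform in the home-region disc
  homes <- with_seed(config$seed + 2L, {
    r <- config$home_radius_km * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    unproject_local(r * sin(th), r * cos(th), config$home_lat, config$home_lon)
  })

  day_plan <- with_seed(config$seed + 3L, {
    ndays <- sample(config$days_range, n, replace = TRUE, prob = config$days_prob)
    lapply(seq_len(n), function(i) {
      nd <- ndays[i]
      mult <- if (config$day_sdlog > 0)
        matrix(stats::rlnorm(nd * 5L, -config$day_sdlog^2 / 2, config$day_sdlog), nd, 5L)
      else matrix(1, nd, 5L)
      exc <- stats::runif(nd) < config$exceptional_trip_rate
      list(ndays = nd, mult = mult, exceptional = exc)
    })
  })

  tg <- truth$targets
  day_truth <- vector("list", n)
  start_date <- as.Date("2016-06-06")
  for (i in seq_len(n)) {
    pid <- cov$participant_id[i]
    plan <- day_plan[[i]]
    dates <- start_date + seq_len(plan$ndays) - 1L
    rows <- vector("list", plan$ndays)
    for (d in seq_len(plan$ndays)) {
      m <- plan$mult[d, ]
      # second-quantized so the CSV round-trip is exact
      agt_d <- round(min(tg$agt[i] * m[1L], config$reg_hours) * 3600) / 3600
      steps_d <- round(tg$steps[i] * m[2L])
      area_d <- tg$life_space_area[i] * m[3L]
      dist_d <- tg$distance[i] * m[4L]
      ar_d <- if (d == 1L) tg$ar_max[i] else tg$ar_max[i] * min(1, m[5L])

      track <- simulate_day_track(homes$lat[i], homes$lon[i], area_d, ar_d,
                                  dist_d, dates[d], config$fix_spacing_km,
                                  exceptional_trip = plan$exceptional[d])
      realized <- attr(track, "realized")
      acts <- simulate_activity_day(agt_d, steps_d, dates[d], config$reg_hours)

      gps_out <- data.frame(
        participant_id = pid,
        timestamp_iso8601 = format(track$time, "%Y-%m-%dT%H:%M:%S+00:00"),
        lat = track$lat, lon = track$lon)
      data.table::fwrite(gps_out,
                         file.path(out_dir, "gps", paste0(pid, "_", dates[d], ".csv")))
      act_out <- data.frame(
        participant_id = pid,
        start_iso8601 = format(acts$start, "%Y-%m-%dT%H:%M:%S+00:00"),
        end_iso8601 = format(acts$end, "%Y-%m-%dT%H:%M:%S+00:00"),
        class = acts$class, met = acts$met, steps = acts$steps)
      data.table::fwrite(act_out,
                         file.path(out_dir, "activity", paste0(pid, "_", dates[d], ".csv")))
      rows[[d]] <- data.frame(participant_id = pid, date = as.character(dates[d]),
                              agt = agt_d, steps = steps_d,
                              life_space_area = realized$area,
                              ar = realized$ar, distance = realized$distance)
    }
    day_truth[[i]] <- do.call(rbind, rows)
  }
  day_truth <- do.call(rbind, day_truth)

  part <- cbind(cov, home_lat = homes$lat, home_lon = homes$lon)
  part <- part[, c("participant_id", "home_lat", "home_lon",
                   config$covariate_spec$name)]
  part <- inject_outliers(part, config$outlier_rate,
                          columns = config$covariate_spec$name,
                          seed = config$seed + 4L)
  omask <- attr(part, "outlier_mask")
  part <- inject_missingness(part, config$missing_rate,
                             config$missing_mechanism,
                             columns = config$covariate_spec$name,
                             seed = config$seed + 5L)
  mmask <- attr(part, "miss_mask")
  data.table::fwrite(part, file.path(out_dir, "participants.csv"))

  truth_out <- list(
    seed = config$seed,
    mechanism = config$missing_mechanism,
    targets = truth$targets,
    std_betas = truth$std_betas,
    effects_sqrt_scale = truth$effects,
    intercepts = as.list(truth$intercepts),
    noise_sd = as.list(truth$noise_sd),
    day_targets = day_truth,
    n_missing_cells = sum(mmask),
    n_outlier_cells = sum(omask))
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(out_dir, "truth") <- truth
  invisible(out_dir)
}
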