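# Physical-activity-based mobility outcomes from classified activity
# intervals (class gait/active/other, MET intensity, step count).  The raw
# accelerometer classification is upstream of this package; intervals are an
# input.
#
# Day handling: registration outside 07:00-21:00 local time is excluded,
# days with under 9 h of registration are invalid, and daily AGT / step
# totals are scaled to a nominal 12-h day before averaging across days.

ACTIVITY_CLASSES <- c("gait", "active", "other")

day_window <- function(date, start_hour = 7, end_hour = 21) {
  d0 <- as.POSIXct(paste0(as.character(date), " 00:00:00"), tz = "UTC")
  c(d0 + start_hour * 3600, d0 + end_hour * 3600)
}

#' Clip activity intervals to the daily registration window
#'
#' Truncates each interval to 07:00-21:00 local time of its own calendar
#' day; fully-outside intervals are dropped. Step counts are prorated by
#' the retained fraction of the interval's duration (the only
#' assumption-free choice for a bout cut by the window).
#'
#' @param intervals data.frame with `start`, `end` (POSIXct local time),
#'   `class`, `met`, `steps`; all on one local day
#' @param start_hour,end_hour window bounds in hours (defaults 7 and 21)
#' @return clipped intervals (possibly zero rows)
#' @export
clip_to_window <- function(intervals, start_hour = 7, end_hour = 21) {
  if (nrow(intervals) == 0L) return(intervals)
  w <- day_window(as.Date(intervals$start[1L], tz = "UTC"), start_hour, end_hour)
  dur0 <- as.numeric(difftime(intervals$end, intervals$start, units = "secs"))
  s <- pmax(intervals$start, w[1L])
  e <- pmin(intervals$end, w[2L])
  keep <- as.numeric(difftime(e, s, units = "secs")) > 0
  out <- intervals[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  frac <- as.numeric(difftime(e[keep], s[keep], units = "secs")) / dur0[keep]
  out$start <- s[keep]; out$end <- e[keep]
  out$steps <- out$steps * frac
  out
}

#' Total registration hours of a (clipped) day
#'
#' Sum of interval durations across all activity classes, including
#' "other". Intervals are required to be non-overlapping (enforced at
#' parse), so the sum equals the covered time.
#'
#' @param intervals clipped intervals of one day
#' @return hours
#' @export
registration_hours <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  sum(as.numeric(difftime(intervals$end, intervals$start, units = "hours")))
}

#' Day-validity rule
#'
#' A day is analysable iff it carries at least `min_hours` (default 9) of
#' registration inside the window; the boundary is inclusive.
#'
#' @param reg_hours registration hours of the day
#' @param min_hours validity threshold, default 9
#' @return logical
#' @export
is_valid_day <- function(reg_hours, min_hours = 9) reg_hours >= min_hours

#' Daily Active-&-Gait Time (AGT)
#'
#' Summed duration of gait and active intervals whose intensity is
#' strictly above `met_threshold` METs (default 3; "higher than" read
#' strictly, so a 3.0-MET bout contributes nothing).
#'
#' @param intervals clipped intervals of one day
#' @param met_threshold MET cutoff, default 3
#' @return hours
#' @export
daily_agt <- function(intervals, met_threshold = 3) {
  if (nrow(intervals) == 0L) return(0)
  sel <- intervals$class %in% c("gait", "active") & intervals$met > met_threshold
  if (!any(sel)) return(0)
  registration_hours(intervals[sel, , drop = FALSE])
}

#' Daily step count
#'
#' Sum of step counts over all retained (clipped) intervals.
#' @param intervals clipped intervals of one day
#' @return steps (fractional after proration)
#' @export
daily_steps <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  sum(intervals$steps)
}

#' Scale a daily value to a nominal 12-hour day
#'
#' `value * 12 / registration_hours`, applied identically to AGT and
#' Steps so that days with unequal wear time are comparable.
#'
#' @param value daily raw value
#' @param reg_hours the day's registration hours (> 0)
#' @return scaled value
#' @export
scale_to_12h <- function(value, reg_hours) {
  if (any(reg_hours <= 0)) stop("scale_to_12h: registration hours must be > 0", call. = FALSE)
  value * 12 / reg_hours
}

#' Per-day activity metrics for one participant
#'
#' Clips to the window, computes registration hours, raw and 12-h-scaled
#' AGT and Steps, and the validity flag (>= `min_hours` of registration).
#'
#' @param intervals data.frame with `date`, `start`, `end`, `class`,
#'   `met`, `steps` for one participant
#' @param start_hour,end_hour registration window (defaults 7, 21)
#' @param min_hours day-validity threshold (default 9)
#' @param met_threshold AGT intensity cutoff (default 3)
#' @return data.frame: `date`, `registration_h`, `agt_raw_h`,
#'   `agt_scaled_h`, `steps_raw`, `steps_scaled`, `valid`
#' @export
activity_day_metrics <- function(intervals, start_hour = 7, end_hour = 21,
                                 min_hours = 9, met_threshold = 3) {
  days <- split(intervals, as.character(intervals$date))
  rows <- lapply(names(days), function(d) {
    cl <- clip_to_window(days[[d]], start_hour, end_hour)
    reg <- registration_hours(cl)
    agt <- daily_agt(cl, met_threshold)
    stp <- daily_steps(cl)
    ok <- is_valid_day(reg, min_hours)
    data.frame(date = d, registration_h = reg, agt_raw_h = agt,
               agt_scaled_h = if (ok) scale_to_12h(agt, reg) else NA_real_,
               steps_raw = stp,
               steps_scaled = if (ok) scale_to_12h(stp, reg) else NA_real_,
               valid = ok, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(date = character(), registration_h = numeric(),
               agt_raw_h = numeric(), agt_scaled_h = numeric(),
               steps_raw = numeric(), steps_scaled = numeric(), valid = logical())
  out[order(out$date), , drop = FALSE]
}

#' Participant-level activity summary
#'
#' Mean of the 12-h-scaled daily AGT and Steps over valid days only;
#' invalid days are excluded before averaging.
#'
#' @param day_metrics output of [activity_day_metrics()]
#' @return one-row data.frame: `agt`, `steps`, `n_valid_days`, `usable`
#' @export
summarize_activity <- function(day_metrics) {
  v <- day_metrics[day_metrics$valid, , drop = FALSE]
  n <- nrow(v)
  data.frame(agt = if (n) mean(v$agt_scaled_h) else NA_real_,
             steps = if (n) mean(v$steps_scaled) else NA_real_,
             n_valid_days = n, usable = n > 0L)
}
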