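# File readers and writers.  CSV dialects:
#   GPS:      participant_id,timestamp_iso8601,lat,lon[,accuracy_m]
#   activity: participant_id,start_iso8601,end_iso8601,class,met,steps
# GPX 1.1 trackpoints are also accepted for GPS input.  Timestamps are
# ISO-8601 with a mandatory offset; the 07:00/21:00 window is defined in
# local civil time, so fixes/intervals are converted to local wall-clock
# time (UTC + offset) on read.

# "2016-06-06T08:01:02+02:00" -> local wall-clock POSIXct (UTC-represented)
parse_iso8601_local <- function(x, what = "timestamp") {
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})(?:\\.\\d+)?(Z|[+-]\\d{2}:?\\d{2})$", x))
  bad <- which(vapply(m, length, integer(1)) == 0L)
  if (length(bad))
    stop(what, ": cannot parse '", x[bad[1L]], "' (ISO-8601 with offset required)",
         call. = FALSE)
  base <- as.POSIXct(paste(vapply(m, `[`, "", 2L), vapply(m, `[`, "", 3L)),
                     tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  off <- vapply(m, `[`, "", 4L)
  secs <- ifelse(off == "Z", 0, {
    sgn <- ifelse(substr(off, 1L, 1L) == "-", -1, 1)
    hh <- as.numeric(substr(off, 2L, 3L))
    mm <- as.numeric(substr(gsub(":", "", substr(off, 4L, 6L)), 1L, 2L))
    sgn * (hh * 3600 + mm * 60)
  })
  structure(list(utc = base, local = base + secs), class = NULL)
}

format_iso8601_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")

#' Read GPS fixes (CSV dialect or GPX 1.1)
#'
#' Fixes are grouped by participant and local calendar date; timestamps
#' must be strictly increasing within a participant (exact duplicates are
#' collapsed with a warning). Coordinates are bounds-checked.
#'
#' @param path a CSV file, a GPX file, or a directory of such files
#' @return data.frame: `participant_id`, `date` (character), `time`
#'   (local wall-clock POSIXct), `lat`, `lon`
#' @export
read_gps <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, "\\.(csv|gpx)$", full.names = TRUE) else path
  if (length(files) == 0L) stop("read_gps: no input files in ", path, call. = FALSE)
  parts <- lapply(files, function(f) {
    if (grepl("\\.gpx$", f, ignore.case = TRUE)) read_gpx_file(f) else read_gps_csv(f)
  })
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, participant_id, time)
  out <- as.data.frame(out)
  dup <- duplicated(out[, c("participant_id", "time")])
  if (any(dup)) {
    warning("read_gps: collapsed ", sum(dup), " duplicate timestamp(s)")
    out <- out[!dup, , drop = FALSE]
  }
  out$date <- format(out$time, "%Y-%m-%d", tz = "UTC")
  out[, c("participant_id", "date", "time", "lat", "lon")]
}

read_gps_csv <- function(f) {
  d <- data.table::fread(f, data.table = FALSE,
                         colClasses = list(character = c("participant_id",
                                                         "timestamp_iso8601")))
  need <- c("participant_id", "timestamp_iso8601", "lat", "lon")
  if (!all(need %in% names(d)))
    stop("read_gps: ", f, ": expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  bad <- which(!is.finite(d$lat) | !is.finite(d$lon) |
                 d$lat < -90 | d$lat > 90 | d$lon < -180 | d$lon > 180)
  if (length(bad))
    stop("read_gps: ", f, ": invalid coordinates at line ", bad[1L] + 1L,
         call. = FALSE)
  t <- parse_iso8601_local(d$timestamp_iso8601, paste0(f, ": timestamp"))
  data.frame(participant_id = d$participant_id, time = t$local,
             lat = d$lat, lon = d$lon, stringsAsFactors = FALSE)
}

read_gpx_file <- function(f) {
  doc <- xml2::read_xml(f)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0L) stop("read_gps: ", f, ": no trackpoints", call. = FALSE)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tms <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  pid <- xml2::xml_text(xml2::xml_find_first(doc, ".//trk/name"))
  if (is.na(pid) || pid == "") pid <- tools::file_path_sans_ext(basename(f))
  if (any(is.na(lat) | is.na(lon) | lat < -90 | lat > 90 | lon < -180 | lon > 180))
    stop("read_gps: ", f, ": invalid coordinates", call. = FALSE)
  t <- parse_iso8601_local(tms, paste0(f, ": time"))
  data.frame(participant_id = pid, time = t$local, lat = lat, lon = lon,
             stringsAsFactors = FALSE)
}

#' Write GPS fixes in the CSV dialect
#' @param fixes data.frame with `participant_id`, `time`, `lat`, `lon`
#' @param path output file
#' @export
write_gps <- function(fixes, path) {
  data.table::fwrite(data.frame(
    participant_id = fixes$participant_id,
    timestamp_iso8601 = format_iso8601_utc(fixes$time),
    lat = fixes$lat, lon = fixes$lon), path)
  invisible(path)
}

#' Write GPS fixes as a GPX 1.1 track
#' @param fixes data.frame with `participant_id`, `time`, `lat`, `lon`
#'   (one participant)
#' @param path output file
#' @export
write_gpx <- function(fixes, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "mobiscope",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  xml2::xml_add_child(trk, "name", as.character(fixes$participant_id[1L]))
  seg <- xml2::xml_add_child(trk, "trkseg")
  for (i in seq_len(nrow(fixes))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.8f", fixes$lat[i]),
                              lon = sprintf("%.8f", fixes$lon[i]))
    xml2::xml_add_child(pt, "time", format_iso8601_utc(fixes$time[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read classified activity intervals (CSV dialect)
#'
#' Validates the class vocabulary, interval orientation (end > start) and
#' non-overlap within each participant-day.
#'
#' @param path a CSV file or a directory of CSV files
#' @return data.frame: `participant_id`, `date`, `start`, `end` (local
#'   wall-clock POSIXct), `class`, `met`, `steps`
#' @export
read_activity <- function(path) {
  files <- if (dir.exists(path)) list.files(path, "\\.csv$", full.names = TRUE) else path
  if (length(files) == 0L) stop("read_activity: no input files in ", path, call. = FALSE)
  parts <- lapply(files, function(f) {
    d <- data.table::fread(f, data.table = FALSE,
                           colClasses = list(character = c("participant_id", "class",
                                                           "start_iso8601",
                                                           "end_iso8601")))
    need <- c("participant_id", "start_iso8601", "end_iso8601", "class", "met", "steps")
    if (!all(need %in% names(d)))
      stop("read_activity: ", f, ": expected columns ", paste(need, collapse = ","),
           call. = FALSE)
    bad <- which(!d$class %in% ACTIVITY_CLASSES)
    if (length(bad))
      stop("read_activity: ", f, ": unknown class '", d$class[bad[1L]],
           "' at line ", bad[1L] + 1L, call. = FALSE)
    s <- parse_iso8601_local(d$start_iso8601, paste0(f, ": start"))
    e <- parse_iso8601_local(d$end_iso8601, paste0(f, ": end"))
    if (any(as.numeric(e$local) <= as.numeric(s$local)))
      stop("read_activity: ", f, ": interval with end <= start", call. = FALSE)
    data.frame(participant_id = d$participant_id, start = s$local, end = e$local,
               class = d$class, met = d$met, steps = d$steps,
               stringsAsFactors = FALSE)
  })
  out <- as.data.frame(data.table::rbindlist(parts))
  out <- out[order(out$participant_id, out$start), , drop = FALSE]
  out$date <- format(out$start, "%Y-%m-%d", tz = "UTC")
  # non-overlap within participant-day
  for (g in split(out, paste(out$participant_id, out$date))) {
    if (nrow(g) > 1L) {
      ov <- which(as.numeric(g$start[-1L]) < as.numeric(g$end[-nrow(g)]))
      if (length(ov))
        stop("read_activity: overlapping intervals for ", g$participant_id[1L],
             " on ", g$date[1L], ": [", format(g$start[ov[1L]]), ", ",
             format(g$end[ov[1L]]), ") overlaps [", format(g$start[ov[1L] + 1L]),
             ", ", format(g$end[ov[1L] + 1L]), ")", call. = FALSE)
    }
  }
  out[, c("participant_id", "date", "start", "end", "class", "met", "steps")]
}

#' Write activity intervals in the CSV dialect
#' @param intervals data.frame with `participant_id`, `start`, `end`,
#'   `class`, `met`, `steps`
#' @param path output file
#' @export
write_activity <- function(intervals, path) {
  data.table::fwrite(data.frame(
    participant_id = intervals$participant_id,
    start_iso8601 = format_iso8601_utc(intervals$start),
    end_iso8601 = format_iso8601_utc(intervals$end),
    class = intervals$class, met = intervals$met, steps = intervals$steps), path)
  invisible(path)
}

#' Read the participant table
#'
#' @param path CSV with `participant_id`, `home_lat`, `home_lon` and
#'   covariate columns
#' @return data.frame
#' @export
read_participants <- function(path) {
  d <- data.table::fread(path, colClasses = list(character = "participant_id"),
                         data.table = FALSE)
  need <- c("participant_id", "home_lat", "home_lon")
  if (!all(need %in% names(d)))
    stop("read_participants: expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (anyDuplicated(d$participant_id))
    stop("read_participants: duplicated participant ids", call. = FALSE)
  check_coords(d$home_lat, d$home_lon, "home")
  d
}

#' Read an analysis/pipeline configuration file (JSON, or YAML if the
#' yaml package is installed)
#'
#' Recognised keys are the arguments of [analysis_config()]; unknown keys
#' are rejected.
#'
#' @param path file ending in .json, .yml or .yaml
#' @return an [analysis_config()]
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_config: YAML support requires the 'yaml' package; use JSON",
           call. = FALSE)
    yaml::read_yaml(path)
  } else stop("read_config: unsupported extension '", ext, "'", call. = FALSE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}
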