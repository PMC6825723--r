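# Pipeline orchestration: study bundle on disk -> per-day and
# per-participant metrics -> predictor table -> association analysis ->
# report files + run log.

#' Locate and validate a study bundle
#'
#' @param dir directory containing `participants.csv`, `gps/`,
#'   `activity/` and optionally `truth.json`
#' @return list of paths, class `mobiscope_bundle`
#' @export
study_bundle <- function(dir) {
  b <- list(dir = dir,
            participants = file.path(dir, "participants.csv"),
            gps = file.path(dir, "gps"),
            activity = file.path(dir, "activity"),
            truth = file.path(dir, "truth.json"))
  if (!file.exists(b$participants))
    stop("study_bundle: missing ", b$participants, call. = FALSE)
  if (!dir.exists(b$gps)) stop("study_bundle: missing ", b$gps, call. = FALSE)
  if (!dir.exists(b$activity)) stop("study_bundle: missing ", b$activity, call. = FALSE)
  if (!file.exists(b$truth)) b$truth <- NULL
  structure(b, class = "mobiscope_bundle")
}

#' Compute the per-participant mobility table of a bundle
#'
#' Reads GPS and activity data, computes the five mobility outcomes per
#' participant (AGT, Steps, life-space area, distance, AR-max), and
#' returns them joined to the covariates. Participants failing a stage
#' are skipped, counted and named, never silently dropped.
#'
#' @param bundle a [study_bundle()]
#' @param radius_km home-filter radius (default 15)
#' @param distance_mode `"path"` or `"net"`
#' @param min_hours activity day-validity threshold (default 9)
#' @return list: `table` (participant x covariates + outcomes),
#'   `gps_days`, `activity_days` (per-day metric frames),
#'   `exclusions` (named character vector id -> reason)
#' @export
compute_mobility <- function(bundle, radius_km = 15, distance_mode = "path",
                             min_hours = 9) {
  part <- read_participants(bundle$participants)
  gps <- read_gps(bundle$gps)
  act <- read_activity(bundle$activity)
  stray <- setdiff(unique(c(gps$participant_id, act$participant_id)),
                   part$participant_id)
  if (length(stray))
    stop("compute_mobility: data for unknown participant(s): ",
         paste(stray, collapse = ", "), call. = FALSE)

  gps_by <- split(gps, gps$participant_id)
  act_by <- split(act, act$participant_id)
  exclusions <- character(0)
  gps_days <- list(); act_days <- list(); rows <- list()

  for (i in seq_len(nrow(part))) {
    pid <- part$participant_id[i]
    res <- tryCatch({
      g <- gps_by[[pid]]; a <- act_by[[pid]]
      if (is.null(g) || nrow(g) == 0L) stop("no GPS data")
      if (is.null(a) || nrow(a) == 0L) stop("no activity data")
      gd <- gps_day_metrics(g, part$home_lat[i], part$home_lon[i],
                            radius_km, distance_mode)
      ad <- activity_day_metrics(a, min_hours = min_hours)
      gs <- summarize_gps(gd)
      as_ <- summarize_activity(ad)
      if (!gs$usable) stop("no usable GPS day")
      if (!as_$usable) stop("no valid activity day (>= ", min_hours, " h)")
      list(gd = cbind(participant_id = pid, gd),
           ad = cbind(participant_id = pid, ad),
           row = data.frame(participant_id = pid,
                            agt = as_$agt, steps = as_$steps,
                            life_space_area = gs$life_space_area,
                            distance = gs$distance, ar_max = gs$ar_max,
                            n_valid_activity_days = as_$n_valid_days,
                            n_gps_days = gs$n_days_distance,
                            stringsAsFactors = FALSE))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) { exclusions[pid] <- res; next }
    gps_days[[pid]] <- res$gd; act_days[[pid]] <- res$ad; rows[[pid]] <- res$row
  }
  table <- merge(part, do.call(rbind, rows), by = "participant_id", sort = TRUE)
  list(table = table,
       gps_days = do.call(rbind, gps_days),
       activity_days = do.call(rbind, act_days),
       exclusions = exclusions)
}

#' Run the full pipeline on a study bundle
#'
#' metrics -> predictor table -> association analysis -> report files.
#' Writes `gps_days.csv`, `activity_days.csv`, `mobility.csv`,
#' `report.json`, `report.md` and `runlog.json` under `out_dir`. Report
#' files are a pure function of bundle + config (byte-identical across
#' re-runs); only the run log carries a wall-clock timestamp.
#'
#' @param bundle a [study_bundle()] or a directory path
#' @param config an [analysis_config()]
#' @param out_dir output directory (default `<bundle>/output`)
#' @param outcomes outcome columns to model (default excludes `distance`,
#'   which is reported as a metric but not modelled by default)
#' @param radius_km,distance_mode,min_hours see [compute_mobility()]
#' @return the report (invisibly), with the mobility table attached as
#'   attribute `"mobility"`
#' @export
run_pipeline <- function(bundle, config = analysis_config(),
                         out_dir = NULL,
                         outcomes = c("agt", "steps", "life_space_area", "ar_max"),
                         radius_km = 15, distance_mode = "path", min_hours = 9) {
  if (is.character(bundle)) bundle <- study_bundle(bundle)
  if (is.null(out_dir)) out_dir <- file.path(bundle$dir, "output")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  mob <- compute_mobility(bundle, radius_km, distance_mode, min_hours)
  reserved <- c("participant_id", "home_lat", "home_lon",
                "n_valid_activity_days", "n_gps_days",
                "agt", "steps", "life_space_area", "distance", "ar_max")
  predictors <- setdiff(names(mob$table), reserved)
  report <- run_association_analysis(mob$table, predictors, outcomes, config)

  recovery <- NULL
  if (!is.null(bundle$truth)) {
    truth <- jsonlite::read_json(bundle$truth, simplifyVector = TRUE)
    recovery <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
      tb <- truth$std_betas[[oc]]
      m <- report$models[[oc]]
      est <- if (is.null(m) || m$empty) numeric(0) else m$beta
      list(true_std_beta = as.list(tb),
           estimated_std_beta = as.list(est),
           true_selected = names(tb),
           estimated_selected = if (is.null(m)) character(0) else m$selected)
    })
  }

  data.table::fwrite(mob$gps_days, file.path(out_dir, "gps_days.csv"))
  data.table::fwrite(mob$activity_days, file.path(out_dir, "activity_days.csv"))
  data.table::fwrite(mob$table, file.path(out_dir, "mobility.csv"))
  write_report_json(report, recovery, mob$exclusions, file.path(out_dir, "report.json"))
  writeLines(report_markdown(report, recovery, mob$exclusions),
             file.path(out_dir, "report.md"))
  runlog <- list(started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                 finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 package_version = as.character(utils::packageVersion("mobiscope")),
                 config = unclass(config),
                 n_participants = report$n,
                 n_excluded = length(mob$exclusions),
                 exclusions = as.list(mob$exclusions),
                 warnings = report$notes)
  jsonlite::write_json(runlog, file.path(out_dir, "runlog.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(report, "mobility") <- mob$table
  attr(report, "out_dir") <- out_dir
  invisible(report)
}

model_to_list <- function(m) {
  if (is.null(m)) return(list(status = "no candidates"))
  if (m$empty) return(list(status = "no variables entered",
                           trace = as.list(m$trace)))
  list(status = "ok", selected = as.list(m$selected),
       std_beta = as.list(unname(m$beta)), p = as.list(unname(m$p)),
       r2 = m$r2, adj_r2 = m$adj_r2, n = m$n, max_vif = m$max_vif,
       residual_shapiro_p = m$shapiro_p,
       trace = lapply(seq_len(nrow(m$trace)), function(i) as.list(m$trace[i, ])))
}

write_report_json <- function(report, recovery, exclusions, path) {
  out <- list(
    n = report$n,
    config = unclass(report$config),
    exclusions = as.list(exclusions),
    normality = lapply(report$normality, function(z)
      list(statistic = z$statistic, p = z$p, pass = z$pass)),
    outliers = report$outliers,
    mcar = report$mcar[c("statistic", "df", "p")],
    correlations = list(rho = as.data.frame(report$correlations$rho),
                        p = as.data.frame(report$correlations$p)),
    candidates = report$candidates,
    models = lapply(report$models, model_to_list),
    notes = report$notes)
  if (!is.null(recovery)) out$recovery <- recovery
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stars_for <- function(p) ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                                                     ifelse(p < 0.05, "*", "")))

report_markdown <- function(report, recovery = NULL, exclusions = character(0)) {
  L <- c("# mobiscope association report", "",
         sprintf("Participants analysed: %d (excluded: %d)",
                 report$n, length(exclusions)),
         sprintf("Outliers: %d/%d cells (%.2f%%), mode=%s",
                 report$outliers$n_flagged, report$outliers$n_cells,
                 100 * report$outliers$rate, report$outliers$mode))
  if (!is.na(report$mcar$p))
    L <- c(L, sprintf("Little's MCAR test: chi2 = %.3f, df = %d, p = %.4f",
                      report$mcar$statistic, report$mcar$df, report$mcar$p))
  L <- c(L, "", "## Correlations (Spearman r_s)", "",
         paste0("| Predictor | ", paste(colnames(report$correlations$rho),
                                        collapse = " | "), " |"),
         paste0("|", paste(rep("---", 1 + ncol(report$correlations$rho)),
                           collapse = "|"), "|"))
  for (pr in rownames(report$correlations$rho)) {
    cells <- sprintf("%.3f%s", report$correlations$rho[pr, ],
                     stars_for(report$correlations$p[pr, ]))
    L <- c(L, paste0("| ", pr, " | ", paste(cells, collapse = " | "), " |"))
  }
  L <- c(L, "", "## Models (stepwise regression, standardized betas)", "")
  for (oc in names(report$candidates)) {
    L <- c(L, paste0("### ", oc), "")
    m <- report$models[[oc]]
    if (is.null(m)) { L <- c(L, "No candidates passed the correlation screen.", ""); next }
    if (m$empty) { L <- c(L, "No variables entered the model.", ""); next }
    L <- c(L, "| Predictor | Beta |", "|---|---|",
           sprintf("| %s | %.3f%s |", m$selected, m$beta, stars_for(m$p)),
           sprintf("| adjusted R^2 | %.3f |", m$adj_r2),
           sprintf("| max VIF | %.3f |", m$max_vif),
           sprintf("| residual Shapiro-Wilk p | %.3f |", m$shapiro_p), "")
  }
  if (!is.null(recovery)) {
    L <- c(L, "## Recovery vs ground truth", "")
    for (oc in names(recovery)) {
      r <- recovery[[oc]]
      L <- c(L, sprintf("- %s: true {%s}, estimated {%s}", oc,
                        paste(r$true_selected, collapse = ", "),
                        paste(r$estimated_selected, collapse = ", ")))
    }
    L <- c(L, "")
  }
  if (length(report$notes)) L <- c(L, "## Notes", "", paste("-", report$notes), "")
  L
}
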