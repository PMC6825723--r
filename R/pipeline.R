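# The association-analysis chain, in the order the mobility outcomes are
# analysed: square-root transforms -> KS normality checks -> Tukey outlier
# screening -> Little's MCAR test -> mean imputation -> Spearman screening
# -> per-outcome stepwise regression with diagnostics.

#' Analysis configuration
#'
#' @param alpha overall significance level (default 0.05)
#' @param alpha_ks significance level of the KS normality screen
#'   (default 0.10; normality screens conventionally use a stricter gate)
#' @param p_enter,p_remove stepwise entry/removal thresholds on the
#'   probability of F (defaults 0.05 / 0.10, the SPSS convention)
#' @param tukey_k Tukey fence multiplier (default 1.5)
#' @param sqrt_columns columns square-root-transformed before analysis
#'   (defaults: the three life-space outcomes, which are right-skewed)
#' @param outlier_mode `"cell"` (default): a flagged value becomes missing
#'   and is mean-imputed, keeping n intact; `"case"`: the whole row is
#'   dropped
#' @param lilliefors use the Lilliefors correction in the KS screen
#' @param adjust_correlations `"none"` (default) or `"BH"`
#' @return list of class `mobiscope_config`
#' @export
analysis_config <- function(alpha = 0.05, alpha_ks = 0.10,
                            p_enter = 0.05, p_remove = 0.10, tukey_k = 1.5,
                            sqrt_columns = c("life_space_area", "distance", "ar_max"),
                            outlier_mode = c("cell", "case"),
                            lilliefors = TRUE,
                            adjust_correlations = c("none", "BH")) {
  stopifnot(p_enter > 0, p_enter <= p_remove, p_remove < 1, tukey_k > 0,
            alpha > 0, alpha < 1, alpha_ks > 0, alpha_ks < 1)
  structure(list(alpha = alpha, alpha_ks = alpha_ks, p_enter = p_enter,
                 p_remove = p_remove, tukey_k = tukey_k,
                 sqrt_columns = sqrt_columns,
                 outlier_mode = match.arg(outlier_mode),
                 lilliefors = lilliefors,
                 adjust_correlations = match.arg(adjust_correlations)),
            class = "mobiscope_config")
}

#' Run the full association analysis
#'
#' Executes the statistical chain on a participant table of covariates and
#' mobility outcomes. Outcomes named in `config$sqrt_columns` are
#' square-root-transformed first; each analysis column is KS-screened for
#' normality and Tukey-screened for outliers (flagged cells set missing by
#' default); Little's MCAR test is run on the pre-imputation missingness;
#' missing cells are mean-imputed; predictors passing the Spearman screen
#' for an outcome become its stepwise candidates. Failures in one
#' outcome's model halt that outcome only.
#'
#' @param table data.frame: one row per participant, predictor and
#'   outcome columns numeric
#' @param predictors,outcomes column names
#' @param config an [analysis_config()]
#' @return object of class `mobiscope_report`: list with elements
#'   `normality`, `outliers`, `mcar`, `correlations`, `models`,
#'   `candidates`, `notes`, `config`, `n`
#' @export
run_association_analysis <- function(table, predictors, outcomes,
                                     config = analysis_config()) {
  stopifnot(inherits(config, "mobiscope_config"))
  missing_cols <- setdiff(c(predictors, outcomes), names(table))
  if (length(missing_cols))
    stop("run_association_analysis: unknown columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  notes <- character(0)
  vars <- c(predictors, outcomes)

  # 1. square-root transforms
  for (cn in intersect(config$sqrt_columns, names(table)))
    table[[cn]] <- sqrt_transform(table[[cn]])

  # 2. KS normality screen (descriptive: recorded, not gating)
  normality <- lapply(stats::setNames(vars, vars), function(cn)
    tryCatch(ks_normality(table[[cn]], config$alpha_ks, config$lilliefors),
             error = function(e) list(statistic = NA_real_, p = NA_real_,
                                      pass = NA, error = conditionMessage(e))))

  # 3. Tukey outlier screen
  n_cells <- 0L; n_flagged <- 0L
  flags <- matrix(FALSE, nrow(table), length(vars), dimnames = list(NULL, vars))
  for (cn in vars) {
    fl <- tryCatch(tukey_outlier_filter(table[[cn]], config$tukey_k),
                   error = function(e) rep(FALSE, nrow(table)))
    flags[, cn] <- fl
    n_cells <- n_cells + sum(!is.na(table[[cn]]))
    n_flagged <- n_flagged + sum(fl)
  }
  if (config$outlier_mode == "cell") {
    for (cn in vars) table[[cn]][flags[, cn]] <- NA_real_
  } else {
    drop <- rowSums(flags) > 0L
    if (any(drop)) {
      notes <- c(notes, sprintf("outlier_mode=case: dropped %d row(s)", sum(drop)))
      table <- table[!drop, , drop = FALSE]
    }
  }
  outliers <- list(n_cells = n_cells, n_flagged = n_flagged,
                   rate = if (n_cells) n_flagged / n_cells else 0,
                   mode = config$outlier_mode)

  # 4. Little's MCAR on the pre-imputation missingness
  mcar <- tryCatch(little_mcar_test(table[, vars, drop = FALSE]),
                   error = function(e) list(statistic = NA_real_, df = NA_integer_,
                                            p = NA_real_, error = conditionMessage(e)))
  if (isTRUE(mcar$degenerate))
    notes <- c(notes, "no missingness: Little's MCAR test degenerate (p = 1)")

  # 5. mean imputation
  table <- mean_impute(table, vars)

  # 6. Spearman screen
  correlations <- spearman_matrix(table, predictors, outcomes)

  # 7. per-outcome stepwise regression
  models <- list(); candidates <- list()
  for (oc in outcomes) {
    cand <- select_candidates(correlations, oc, config$alpha,
                              config$adjust_correlations)
    candidates[[oc]] <- cand
    if (length(cand) == 0L) {
      notes <- c(notes, sprintf("%s: no candidates passed the correlation screen", oc))
      models[oc] <- list(NULL)
      next
    }
    models[oc] <- list(tryCatch(
      stepwise_regression(table[[oc]], table[, cand, drop = FALSE],
                          config$p_enter, config$p_remove),
      error = function(e) {
        notes <<- c(notes, sprintf("%s: stepwise failed: %s", oc, conditionMessage(e)))
        NULL
      }))
  }

  structure(list(normality = normality, outliers = outliers, mcar = mcar,
                 correlations = correlations, candidates = candidates,
                 models = models, notes = notes, config = config,
                 n = nrow(table)),
            class = "mobiscope_report")
}

#' @export
print.mobiscope_report <- function(x, ...) {
  cat("mobiscope association analysis (n =", x$n, ")\n")
  cat(sprintf("Outliers: %d/%d cells flagged (%.2f%%), mode=%s\n",
              x$outliers$n_flagged, x$outliers$n_cells,
              100 * x$outliers$rate, x$outliers$mode))
  if (!is.null(x$mcar$p) && !is.na(x$mcar$p))
    cat(sprintf("Little's MCAR: chi2 = %.2f, df = %d, p = %.3f\n",
                x$mcar$statistic, x$mcar$df, x$mcar$p))
  cat("\n")
  print(x$correlations)
  for (oc in names(x$models)) {
    cat("\nOutcome:", oc, "\n")
    if (is.null(x$models[[oc]])) cat("  (no model)\n") else print(x$models[[oc]])
  }
  if (length(x$notes)) cat("\nNotes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
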