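# Pre-regression data preparation: square-root transforms for the
# right-skewed life-space outcomes, Tukey fence outlier screening, and mean
# imputation of missing covariates.

#' Square-root transform of a non-negative column
#'
#' Element-wise square root; `NA` propagates. Used on life-space area,
#' total distance and maximum action range, which are right-skewed on
#' their natural scales.
#'
#' @param x numeric vector, all non-missing values >= 0
#' @return sqrt(x)
#' @export
sqrt_transform <- function(x) {
  bad <- which(!is.na(x) & x < 0)
  if (length(bad))
    stop("sqrt_transform: negative value at position ", bad[1L], call. = FALSE)
  sqrt(x)
}

#' Tukey fences for a numeric vector
#'
#' `[Q1 - k*IQR, Q3 + k*IQR]` with type-7 (linear-interpolation)
#' quartiles, the R default.
#'
#' @param x numeric vector (NAs ignored)
#' @param k fence multiplier, conventionally 1.5
#' @return length-2 numeric vector (lower, upper)
#' @export
tukey_fences <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  c(q[1L] - k * iqr, q[2L] + k * iqr)
}

#' Flag outliers by Tukey's fences
#'
#' Flags values strictly outside the fences (boundary values are kept;
#' for a constant vector the fences collapse onto the value and nothing
#' is flagged). Missing values are never flagged.
#'
#' @param x numeric vector with >= 4 non-missing values
#' @param k fence multiplier, default 1.5
#' @return logical vector, `TRUE` = outlier
#' @export
tukey_outlier_filter <- function(x, k = 1.5) {
  if (sum(!is.na(x)) < 4L)
    stop("tukey_outlier_filter: need >= 4 non-missing values", call. = FALSE)
  f <- tukey_fences(x, k)
  out <- !is.na(x) & (x < f[1L] | x > f[2L])
  out
}

#' Mean-impute missing cells of a numeric table
#'
#' Each missing cell is replaced by the observed mean of its column, so
#' column means are unchanged by imputation.
#'
#' @param table data.frame; non-numeric columns are passed through
#' @param columns columns to impute (default: all numeric columns)
#' @return the imputed table
#' @export
mean_impute <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  for (cn in columns) {
    x <- table[[cn]]
    if (!anyNA(x)) next
    obs <- x[!is.na(x)]
    if (length(obs) == 0L)
      stop("mean_impute: column '", cn, "' is fully missing", call. = FALSE)
    x[is.na(x)] <- mean(obs)
    table[[cn]] <- x
  }
  table
}
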