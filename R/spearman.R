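# Spearman correlation screening: every (predictor, outcome) pair gets a
# rank correlation and a two-sided p-value; predictors significantly
# correlated with an outcome become that outcome's stepwise candidates.

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties),
#' computed over complete pairs; the two-sided p-value uses
#' `t = rho * sqrt((n-2)/(1-rho^2))` with n-2 df — the standard
#' approximation for cohort-sized samples.
#'
#' @param x,y numeric vectors
#' @return list: `rho`, `p`, `n` (complete pairs); `rho` is NA for a
#'   zero-variance margin
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 5L) stop("spearman_cor: need >= 5 complete pairs", call. = FALSE)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Spearman correlation matrix between predictors and outcomes
#'
#' @param table data.frame holding both sets of columns
#' @param predictors,outcomes column names
#' @return object of class `mobiscope_corr`: list of matrices `rho`, `p`,
#'   `n` (predictors x outcomes)
#' @export
spearman_matrix <- function(table, predictors, outcomes) {
  miss <- setdiff(c(predictors, outcomes), names(table))
  if (length(miss))
    stop("spearman_matrix: unknown columns: ", paste(miss, collapse = ", "), call. = FALSE)
  rho <- p <- n <- matrix(NA_real_, length(predictors), length(outcomes),
                          dimnames = list(predictors, outcomes))
  for (i in seq_along(predictors)) for (j in seq_along(outcomes)) {
    s <- spearman_cor(table[[predictors[i]]], table[[outcomes[j]]])
    rho[i, j] <- s$rho; p[i, j] <- s$p; n[i, j] <- s$n
  }
  structure(list(rho = rho, p = p, n = n), class = "mobiscope_corr")
}

#' @export
print.mobiscope_corr <- function(x, digits = 3, ...) {
  cat("Spearman correlations (predictors x outcomes)\n")
  stars <- ifelse(is.na(x$p), " ",
                  ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", "")))
  m <- matrix(paste0(formatC(x$rho, digits = digits, format = "f"), stars),
              nrow(x$rho), ncol(x$rho), dimnames = dimnames(x$rho))
  print(m, quote = FALSE)
  invisible(x)
}

#' Select stepwise candidates from the correlation screen
#'
#' Predictors whose Spearman p-value for the given outcome is below
#' `alpha`, in original column order. No multiplicity correction is
#' applied by default (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param corr a [spearman_matrix()] result
#' @param outcome outcome column name
#' @param alpha screening level, default 0.05
#' @param adjust `"none"` (default) or `"BH"`
#' @return character vector of predictor names (possibly empty)
#' @export
select_candidates <- function(corr, outcome, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pv <- corr$p[, outcome]
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  rownames(corr$p)[!is.na(pv) & pv < alpha]
}
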