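# Stepwise multiple regression in the classical probability-of-F flavour:
# at each step the candidate with the smallest partial-F p-value enters if
# that p-value is below `p_enter`; after every entry, included variables
# whose p-value has drifted above `p_remove` are dropped.  Coefficients are
# reported standardized (outcome and predictors z-scored).

# Least squares with intercept via QR; returns what the selection loop and
# the final report need.
ols_fit <- function(y, X) {
  n <- length(y)
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xd)
  if (qr_$rank < ncol(Xd))
    return(list(singular = TRUE, rank = qr_$rank))
  beta <- qr.coef(qr_, y)
  res <- y - Xd %*% beta
  rdf <- n - ncol(Xd)
  s2 <- sum(res^2) / rdf
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(pmax(0, diag(XtXinv)) * s2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), rdf)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  list(singular = FALSE, coef = beta, se = se, t = tval, p = pval,
       residuals = as.numeric(res), r2 = r2, rdf = rdf, s2 = s2)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)` for a model with `p` predictors
#' fitted to `n` observations.
#'
#' @param r2 unadjusted R-squared
#' @param n number of observations
#' @param p number of predictors (excluding the intercept)
#' @return adjusted R-squared
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted_r2: need n > p + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing
#' predictor `k` on the remaining predictors. Perfect collinearity is
#' reported as `Inf` with a warning.
#'
#' @param X numeric matrix or data.frame of >= 2 predictors
#' @return named numeric vector of VIFs
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 2L) stop("vif: need >= 2 predictors", call. = FALSE)
  if (nrow(X) <= k) stop("vif: need more rows than predictors", call. = FALSE)
  out <- numeric(k)
  names(out) <- colnames(X)
  for (j in seq_len(k)) {
    # projection onto the others' column space; rank-deficient designs
    # (e.g. duplicated columns elsewhere) are handled by the pivoted QR
    qr_ <- qr(cbind(1, X[, -j, drop = FALSE]))
    res <- qr.resid(qr_, X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
    if (r2 >= 1 - 1e-12) {
      warning("vif: predictor '", colnames(X)[j],
              "' is perfectly collinear with the others")
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

#' Stepwise multiple regression with p-to-enter / p-to-remove
#'
#' Forward selection with backward pruning: enter the candidate with the
#' smallest partial-F p-value while it is below `p_enter`; after each
#' entry remove (one at a time, worst first) any included variable whose
#' p-value exceeds `p_remove`. Stops when no entry or removal changes the
#' model; a cycle guard forbids revisiting an earlier model state. The
#' final model is refit on z-scored outcome and predictors, so the
#' reported coefficients are standardized betas.
#'
#' @param y numeric outcome vector (no NAs)
#' @param X data.frame or matrix of candidate predictors (no NAs)
#' @param p_enter entry threshold on the partial-F p-value (default 0.05)
#' @param p_remove removal threshold (default 0.10); must be >= p_enter
#' @return object of class `mobiscope_stepwise`: list with `selected`
#'   (in entry order), `beta` (standardized), `p` (per coefficient),
#'   `r2`, `adj_r2`, `n`, `max_vif`, `shapiro_p` (residual normality),
#'   `trace` (data.frame of enter/remove events), `empty` flag
#' @export
stepwise_regression <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  if (anyNA(y) || anyNA(X))
    stop("stepwise_regression: missing values must be handled upstream", call. = FALSE)
  if (p_enter > p_remove)
    stop("stepwise_regression: p_enter must be <= p_remove", call. = FALSE)
  n <- length(y)
  cand <- names(X)
  if (n <= length(cand) + 2L)
    stop("stepwise_regression: need n > candidates + 2", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("stepwise_regression: outcome is constant", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("stepwise_regression: constant candidate(s): ",
         paste(cand[sds == 0], collapse = ", "), call. = FALSE)

  # selection on z-scored data; invariant under affine rescaling anyway
  Z <- scale(as.matrix(X))
  zy <- as.numeric(scale(y))

  included <- character(0)
  trace <- list()
  seen <- character(0)                      # visited model states (cycle guard)
  state_key <- function(s) paste(sort(s), collapse = "|")
  seen <- state_key(included)

  repeat {
    changed <- FALSE
    # --- entry step
    excl <- setdiff(cand, included)
    if (length(excl)) {
      pv <- vapply(excl, function(v) {
        f <- ols_fit(zy, Z[, c(included, v), drop = FALSE])
        if (isTRUE(f$singular)) return(1)
        unname(f$p[v])
      }, numeric(1))
      best <- which.min(pv)
      if (pv[best] < p_enter) {
        candidate_state <- state_key(c(included, excl[best]))
        if (!(candidate_state %in% seen)) {
          included <- c(included, excl[best])
          seen <- c(seen, candidate_state)
          trace[[length(trace) + 1L]] <-
            data.frame(step = length(trace) + 1L, action = "enter",
                       variable = excl[best], p = unname(pv[best]))
          changed <- TRUE
        }
      }
    }
    # --- removal step(s)
    repeat {
      if (length(included) == 0L) break
      f <- ols_fit(zy, Z[, included, drop = FALSE])
      pv <- f$p[included]
      worst <- which.max(pv)
      if (pv[worst] <= p_remove) break
      candidate_state <- state_key(included[-worst])
      if (candidate_state %in% seen) break       # would revisit: stop cycling
      trace[[length(trace) + 1L]] <-
        data.frame(step = length(trace) + 1L, action = "remove",
                   variable = included[worst], p = unname(pv[worst]))
      included <- included[-worst]
      seen <- c(seen, candidate_state)
      changed <- TRUE
    }
    if (!changed) break
  }

  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(),
               variable = character(), p = numeric())

  if (length(included) == 0L) {
    return(structure(list(selected = character(0), beta = numeric(0),
                          p = numeric(0), r2 = 0, adj_r2 = 0, n = n,
                          max_vif = NA_real_, shapiro_p = NA_real_,
                          trace = trace, empty = TRUE),
                     class = "mobiscope_stepwise"))
  }

  f <- ols_fit(zy, Z[, included, drop = FALSE])
  mv <- if (length(included) >= 2L) max(vif(Z[, included, drop = FALSE])) else 1
  swp <- tryCatch(shapiro_wilk(f$residuals)$p, error = function(e) NA_real_)
  structure(list(selected = included,
                 beta = f$coef[included],
                 p = f$p[included],
                 r2 = f$r2,
                 adj_r2 = adjusted_r2(f$r2, n, length(included)),
                 n = n, max_vif = mv, shapiro_p = swp,
                 trace = trace, empty = FALSE),
            class = "mobiscope_stepwise")
}

#' @export
print.mobiscope_stepwise <- function(x, digits = 3, ...) {
  if (x$empty) { cat("Stepwise model: no candidates entered\n"); return(invisible(x)) }
  stars <- ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))
  cat("Stepwise model (n =", x$n, ")\n")
  for (i in seq_along(x$selected))
    cat(sprintf("  %-20s beta = %s%s\n", x$selected[i],
                formatC(x$beta[i], digits = digits, format = "f"), stars[i]))
  cat(sprintf("  adjusted R^2 = %s, max VIF = %s, residual Shapiro-Wilk p = %s\n",
              formatC(x$adj_r2, digits = digits, format = "f"),
              formatC(x$max_vif, digits = digits, format = "f"),
              formatC(x$shapiro_p, digits = digits, format = "f")))
  invisible(x)
}
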