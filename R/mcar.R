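# Little's MCAR test: compares the observed-variable means of each
# missingness pattern against the EM-estimated grand mean, pooling the
# squared standardized deviations into one chi-square statistic.  A
# significant result argues against "missing completely at random" and
# hence against unbiasedness of simple imputation.

#' EM estimation of a multivariate-normal mean and covariance with
#' missing values
#'
#' Standard EM for incomplete MVN data, grouped by missingness pattern
#' for speed. ML covariance (divisor n).
#'
#' @param Y numeric matrix with NAs; rows with no observed value are dropped
#' @param max_iter,tol convergence controls
#' @return list: `mu`, `sigma`, `iterations`, `converged`
#' @export
em_norm <- function(Y, max_iter = 200L, tol = 1e-6) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  Y <- Y[rowSums(!is.na(Y)) > 0L, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (n < 2L) stop("em_norm: need >= 2 usable rows", call. = FALSE)
  mu <- colMeans(Y, na.rm = TRUE)
  sigma <- stats::cov(Y, use = "pairwise.complete.obs") * (n - 1) / n
  sigma[!is.finite(sigma)] <- 0
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v == 0] <- 1
  diag(sigma)[diag(sigma) <= 0] <- v[diag(sigma) <= 0]
  # guard against an indefinite pairwise-complete start
  e <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= 1e-10 * max(abs(e))) sigma <- diag(v, p)

  miss <- is.na(Y)
  pat <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)

  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    S1 <- numeric(p); S2 <- matrix(0, p, p)
    for (rows in groups) {
      m <- miss[rows[1L], ]; o <- !m
      Yg <- Y[rows, , drop = FALSE]
      if (!any(m)) {
        S1 <- S1 + colSums(Yg)
        S2 <- S2 + crossprod(Yg)
        next
      }
      B <- sigma[m, o, drop = FALSE] %*% solve(sigma[o, o, drop = FALSE])
      Cm <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
      Yo <- Yg[, o, drop = FALSE]
      Em <- matrix(mu[m], nrow(Yg), sum(m), byrow = TRUE) +
        sweep(Yo, 2L, mu[o]) %*% t(B)
      Yfull <- Yg
      Yfull[, m] <- Em
      S1 <- S1 + colSums(Yfull)
      S2cur <- crossprod(Yfull)
      S2cur[m, m] <- S2cur[m, m] + nrow(Yg) * Cm
      S2 <- S2 + S2cur
    }
    mu_new <- S1 / n
    sigma_new <- S2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  dimnames(sigma) <- list(colnames(Y), colnames(Y))
  names(mu) <- colnames(Y)
  list(mu = mu, sigma = sigma, iterations = it, converged = converged)
}

#' Little's MCAR test
#'
#' Computes `d2 = sum_j n_j (ybar_j - mu_j)' Sigma_j^{-1} (ybar_j - mu_j)`
#' over missingness patterns `j`, with `mu`, `Sigma` estimated by EM on
#' the incomplete data, and compares it to a chi-square with
#' `sum_j p_j - p` degrees of freedom. A small p-value rejects MCAR.
#'
#' @param table data.frame or matrix of numeric variables with NAs (only
#'   the columns to be tested; identifiers excluded by the caller)
#' @return list: `statistic`, `df`, `p`, `n_patterns`, `degenerate`
#'   (TRUE when there is no missingness to test: statistic 0, p 1)
#' @export
little_mcar_test <- function(table) {
  Y <- as.matrix(as.data.frame(table)[vapply(as.data.frame(table), is.numeric, logical(1))])
  Y <- Y[rowSums(!is.na(Y)) > 0L, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (p < 2L) stop("little_mcar_test: need >= 2 numeric variables", call. = FALSE)
  miss <- is.na(Y)
  pat <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  if (length(groups) < 2L || !anyNA(Y))
    return(list(statistic = 0, df = 0L, p = 1, n_patterns = length(groups),
                degenerate = TRUE))
  fit <- em_norm(Y)
  d2 <- 0; df <- 0L
  for (rows in groups) {
    o <- !miss[rows[1L], ]
    if (!any(o)) next
    ybar <- colMeans(Y[rows, o, drop = FALSE])
    dev <- ybar - fit$mu[o]
    d2 <- d2 + length(rows) *
      drop(crossprod(dev, solve(fit$sigma[o, o, drop = FALSE], dev)))
    df <- df + sum(o)
  }
  df <- df - p
  list(statistic = d2, df = df, p = stats::pchisq(d2, df, lower.tail = FALSE),
       n_patterns = length(groups), degenerate = FALSE)
}
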