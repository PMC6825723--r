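# Normality checks used by the analysis chain: a Kolmogorov-Smirnov test of
# composite normality (Lilliefors-corrected, since mean and sd are estimated
# from the sample) for the marginal distributions, and Shapiro-Wilk for
# regression residuals.

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against `N(mean(x), sd(x))`. Because the
#' parameters are estimated, the classical KS null distribution is wrong;
#' the p-value uses the Dallal-Wilkinson (1986) approximation with
#' Stephens' (1974) modification for p > 0.1 — the standard Lilliefors
#' implementation. Set `lilliefors = FALSE` for the naive (conservative)
#' classical p-value.
#'
#' @param x numeric vector, >= 5 non-missing values
#' @param alpha significance level for the pass flag (default 0.10, the
#'   convention of using a stricter gate for normality screening)
#' @param lilliefors use the estimated-parameter correction (default TRUE)
#' @return list: `statistic`, `p`, `pass` (p > alpha), `n`, `degenerate`
#'   (TRUE for a zero-variance sample, which is reported as a hard fail)
#' @export
ks_normality <- function(x, alpha = 0.10, lilliefors = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5L) stop("ks_normality: need >= 5 non-missing values", call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p = 0, pass = FALSE, n = n, degenerate = TRUE))
  x <- sort(x)
  z <- stats::pnorm(x, mean(x), stats::sd(x))
  D <- max(seq_len(n) / n - z, z - (seq_len(n) - 1L) / n)
  if (!lilliefors) {
    p <- stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
  } else {
    p <- lilliefors_pvalue(D, n)
  }
  list(statistic = D, p = p, pass = p > alpha, n = n, degenerate = FALSE)
}

# Dallal & Wilkinson (1986) analytic approximation, with Stephens (1974)
# for the upper tail (p > 0.1), as used by the reference Lilliefors
# implementations.
#' @keywords internal
lilliefors_pvalue <- function(D, n) {
  if (n > 100L) { Kd <- D * (n / 100)^0.49; nd <- 100 } else { Kd <- D; nd <- n }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
    else if (KK <= 0.5)
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 - 138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9)
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 + 94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31)
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 - 12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  min(1, max(0, p))
}

#' Shapiro-Wilk normality test
#'
#' Royston's AS R94 algorithm (delegated to [stats::shapiro.test()],
#' which implements exactly that), with the sample-size contract made
#' explicit. Used on regression residuals.
#'
#' @param x numeric vector, 3 <= n <= 5000 after removing NAs
#' @return list: `statistic` (W), `p`, `n`
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("shapiro_wilk: sample size must be in [3, 5000], got ", n, call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value, n = n)
}
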