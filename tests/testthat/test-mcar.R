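mvn_mcar <- function(n, p = 4, rate = 0.1, rho = 0.3) {
  Y <- matrix(rnorm(n * p), n, p) %*% chol(rho + diag(1 - rho, p))
  Y[matrix(runif(n * p) < rate, n, p)] <- NA
  as.data.frame(Y)
}

test_that("EM recovers mean and covariance under MCAR", {
  set.seed(21)
  Y <- matrix(rnorm(2000 * 3), 2000, 3) %*% chol(0.4 + diag(0.6, 3))
  Y <- sweep(Y, 2, c(1, -2, 5), `+`)
  Ym <- Y; Ym[matrix(runif(6000) < 0.2, 2000, 3)] <- NA
  fit <- em_norm(Ym)
  expect_true(fit$converged)
  expect_equal(unname(fit$mu), c(1, -2, 5), tolerance = 0.15)
  expect_equal(unname(diag(fit$sigma)), rep(1, 3), tolerance = 0.15)
  expect_equal(fit$sigma[1, 2], 0.4, tolerance = 0.15)
})

test_that("Little's test: degenerate on complete data, detects MNAR", {
  df <- as.data.frame(matrix(rnorm(100), 25, 4))
  r <- little_mcar_test(df)
  expect_true(r$degenerate)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # strong MNAR masking is rejected more often than not (power simulation)
  set.seed(22)
  pw <- mean(replicate(60, {
    d <- as.data.frame(matrix(rnorm(500 * 4), 500, 4) %*% chol(0.3 + diag(0.7, 4)))
    p <- little_mcar_test(inject_missingness(d, 0.05, "mnar"))$p
    p <= 0.05
  }))
  expect_gt(pw, 0.5)
})

test_that("Little's test df equals sum of pattern sizes minus p", {
  set.seed(23)
  df <- mvn_mcar(120, p = 3, rate = 0.15)
  r <- little_mcar_test(df)
  miss <- is.na(as.matrix(df))
  keep <- rowSums(!miss) > 0
  pat <- apply(miss[keep, ], 1, paste, collapse = "")
  df_expect <- sum(tapply(rowSums(!miss[keep, ]), pat, function(v) v[1])) - 3
  expect_equal(r$df, df_expect)
  expect_gte(r$statistic, 0)
})
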