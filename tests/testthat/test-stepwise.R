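test_that("adjusted R2: arithmetic, fixed points, domain", {
  expect_equal(adjusted_r2(0.5, 101, 2), 1 - 0.5 * 100 / 98)
  expect_equal(round(adjusted_r2(0.5, 101, 2), 6), 0.489796)
  expect_equal(adjusted_r2(1, 50, 5), 1)
  expect_equal(adjusted_r2(0.37, 40, 0), 0.37)
  expect_error(adjusted_r2(0.5, 4, 3), "n > p")
})

test_that("VIF: orthogonal, collinear, closed form, oracle", {
  set.seed(41)
  # columns orthogonal to each other and to the intercept (centred)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  colnames(Q) <- c("q1", "q2", "q3")
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-9)
  # duplicated predictor: both copies flagged infinite, the third untouched
  X <- cbind(x1 = rnorm(20), x2 = rnorm(20))
  w <- capture_warnings(v <- vif(cbind(X, x3 = X[, 1])))
  expect_match(w, "collinear", all = TRUE)
  expect_true(is.infinite(v["x1"]) && is.infinite(v["x3"]))
  expect_true(is.finite(v["x2"]))
  # correlated pair: VIF = 1/(1-r^2)
  for (i in 1:20) {
    Z <- matrix(rnorm(200), 100, 2)
    r <- runif(1, -0.9, 0.9)
    W <- cbind(a = Z[, 1], b = r * Z[, 1] + sqrt(1 - r^2) * Z[, 2])
    robs <- cor(W[, 1], W[, 2])
    expect_equal(unname(vif(W)), rep(1 / (1 - robs^2), 2), tolerance = 1e-9)
    expect_equal(unname(vif(W)), unname(brute_vif(W)), tolerance = 1e-9)
  }
})

test_that("single strong candidate: standardized beta equals Pearson r", {
  set.seed(42)
  x <- rnorm(100)
  y <- 0.8 * x + rnorm(100, 0, 0.5)
  m <- stepwise_regression(y, data.frame(x = x))
  expect_equal(m$selected, "x")
  expect_equal(unname(m$beta["x"]), cor(x, y), tolerance = 1e-10)
})

test_that("stepwise soundness at termination", {
  set.seed(43)
  for (i in 1:10) {
    n <- 150
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("v", 1:6)
    y <- 0.5 * X$v1 - 0.4 * X$v2 + rnorm(n)
    m <- stepwise_regression(y, X)
    if (m$empty) next
    # every retained predictor below the removal threshold
    expect_true(all(m$p <= 0.10 + 1e-12))
    # every excluded candidate would not enter
    Z <- scale(as.matrix(X)); zy <- as.numeric(scale(y))
    for (v in setdiff(names(X), m$selected)) {
      f <- summary(lm(zy ~ Z[, c(m$selected, v)]))
      p_in <- f$coefficients[nrow(f$coefficients), 4]
      expect_gte(p_in, 0.05 - 1e-12)
    }
  }
})

test_that("null model: false-entry proportion tracks an lm()-based oracle", {
  set.seed(44)
  reps <- 150; n <- 200; k <- 10
  mine <- logical(reps); oracle <- logical(reps)
  for (r in seq_len(reps)) {
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(X) <- paste0("v", 1:k)
    y <- rnorm(n)
    mine[r] <- !stepwise_regression(y, X)$empty
    # oracle: does any single-candidate lm() show p < 0.05 at step 1?
    p1 <- vapply(X, function(x) summary(lm(y ~ x))$coefficients[2, 4], numeric(1))
    oracle[r] <- any(p1 < 0.05)
  }
  expect_lt(abs(mean(mine) - mean(oracle)), 0.05)
})

test_that("contracts: constant candidates, missing data, thresholds", {
  y <- rnorm(30)
  expect_error(stepwise_regression(y, data.frame(a = rep(1, 30))), "constant")
  expect_error(stepwise_regression(c(y[-1], NA), data.frame(a = rnorm(30))), "missing")
  expect_error(stepwise_regression(y, data.frame(a = rnorm(30)),
                                   p_enter = 0.2, p_remove = 0.1), "p_enter")
  expect_error(stepwise_regression(rnorm(5),
                                   as.data.frame(matrix(rnorm(25), 5, 5))),
               "candidates")
})
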