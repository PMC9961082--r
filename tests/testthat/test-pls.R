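test_that("PLS1 limits: univariate slope, OLS at full rank, exact fit", {
  set.seed(10)
  x <- rnorm(12)
  y <- 3 * x + rnorm(12, 0, 0.2)
  m1 <- fitPls(matrix(x), y, 1)
  ols1 <- cov(x, y) / var(x)
  expect_equal(coef(m1)[1], ols1, tolerance = 1e-10)

  X <- matrix(rnorm(40), 10)
  beta <- c(1, -2, 0.5, 3)
  yy <- as.numeric(X %*% beta) + rnorm(10, 0, 0.3)
  m4 <- fitPls(X, yy, 4)
  Xc <- scale(X, scale = FALSE)
  ols4 <- solve(crossprod(Xc), crossprod(Xc, yy - mean(yy)))
  expect_equal(coef(m4), as.numeric(ols4), tolerance = 1e-8)

  yexact <- as.numeric(X %*% beta)
  mex <- fitPls(X, yexact, 4)
  expect_equal(predict(mex, X), yexact, tolerance = 1e-8)
})

test_that("prediction paths agree and centering identities hold", {
  set.seed(11)
  X <- matrix(rnorm(120), 15)
  y <- rnorm(15)
  m <- fitPls(X, y, 3)
  # coefficient path equals the weights/loadings score path
  perLv <- sportnir:::.plsPredictPerLv(m, X)
  expect_equal(perLv[, 3], predict(m, X), tolerance = 1e-8)
  # a sample at the training mean predicts the response mean
  expect_equal(predict(m, matrix(m@xMeans, 1)), mean(y), tolerance = 1e-10)
  # score columns are mutually orthogonal
  tt <- crossprod(scores(m))
  expect_lt(max(abs(tt[upper.tri(tt)])), 1e-8 * max(diag(tt)))
  expect_error(predict(m, X[, 1:5]), "variables")
})

test_that("PLS is invariant to block scaling and monotone in training error", {
  set.seed(12)
  X <- matrix(rnorm(200), 20)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(20)
  base <- fitPls(X, y, 4)
  scaledX <- 37.5 * X
  scaled <- fitPls(scaledX, y, 4)
  expect_equal(predict(scaled, scaledX), predict(base, X), tolerance = 1e-8)
  rmseAt <- vapply(1:8, function(a) {
    sqrt(mean((predict(fitPls(X, y, a), X) - y)^2))
  }, 0)
  expect_true(all(diff(rmseAt) <= 1e-10))
})

test_that("fit preconditions are enforced", {
  X <- matrix(rnorm(40), 10)
  expect_error(fitPls(X, rnorm(10), 10), "exceeds")
  expect_error(fitPls(X, rep(1, 10), 2), "zero variance")
  # rank-deficient X: asking beyond the true rank fails informatively
  Xr <- cbind(X[, 1], X[, 1], X[, 2], X[, 2])
  expect_error(fitPls(Xr, rnorm(10), 4), "rank")
})

test_that("regression metrics match hand computations", {
  perfect <- regressionMetrics(1:5, 1:5)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$r2, 1)
  off <- regressionMetrics(1:5, 1:5 + 100)
  expect_equal(off$rmse, 100)
  expect_equal(off$bias, 100)
  hand <- regressionMetrics(c(0, 1, 2), c(0, 2, 2))
  expect_equal(hand$rmse, sqrt(1 / 3))
  expect_equal(hand$bias, 1 / 3)
  expect_equal(hand$r2, 0.5)
  # calibration-mean convention shifts the reference sum of squares
  alt <- regressionMetrics(c(0, 1, 2), c(0, 2, 2), "calibration-mean",
                           calibrationMean = 0)
  expect_equal(alt$r2, 1 - 1 / 5)
  expect_error(regressionMetrics(c(1, 1), c(1, 2)), "zero total")
  expect_error(regressionMetrics(1:3, 1:2), "length")
})

test_that("VIP satisfies its normalization and concentrated-weight limits", {
  set.seed(13)
  X <- matrix(rnorm(120), 20)
  y <- as.numeric(X %*% rnorm(6)) + rnorm(20, 0, 0.5)
  m <- fitPls(X, y, 3)
  v <- vip(m)
  expect_equal(mean(v$scores^2), 1, tolerance = 1e-10)
  expect_true(all(v$scores >= 0))
  # brute-force formula evaluation
  ssy <- m@yLoadings^2 * colSums(m@scores^2)
  direct <- sqrt(6 * sapply(1:6, function(j) {
    sum(ssy * (m@weights[j, ]^2 / colSums(m@weights^2))) / sum(ssy)
  }))
  expect_equal(v$scores, direct, tolerance = 1e-10)
  # one informative variable among p: its VIP is sqrt(p), rest 0
  p <- 7
  Xs <- matrix(rnorm(20 * p, 0, 1e-4), 20)
  Xs[, 4] <- rnorm(20)
  ys <- 2 * Xs[, 4]
  vs <- vip(fitPls(Xs, ys, 1))
  expect_equal(vs$scores[4], sqrt(p), tolerance = 1e-3)
  expect_lt(max(vs$scores[-4]), 0.01)
})

test_that("PLS models serialize to JSON and back", {
  set.seed(14)
  X <- matrix(rnorm(60), 12)
  y <- rnorm(12)
  m <- fitPls(X, y, 2)
  f <- withr::local_tempfile(fileext = ".json")
  writePlsModel(m, f)
  m2 <- readPlsModel(f)
  expect_equal(coef(m2), coef(m))
  expect_equal(predict(m2, X), predict(m, X))
})
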