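test_that("SNV standardizes rows and is affine-invariant", {
  expect_equal(snv(matrix(1:3, nrow = 1)), matrix(c(-1, 0, 1), nrow = 1))
  set.seed(1)
  X <- matrix(rnorm(200), 5)
  Z <- snv(X)
  expect_equal(rowMeans(Z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(Z, 1, sd), rep(1, 5), tolerance = 1e-12)
  # idempotence on already-standardized rows
  expect_equal(snv(Z), Z, tolerance = 1e-12)
  # per-spectrum gain/offset invariance, property over random draws
  for (i in 1:20) {
    a <- runif(5, 0.1, 10)
    b <- rnorm(5, 0, 50)
    expect_equal(snv(a * X + b), Z, tolerance = 1e-9)
  }
  bad <- X
  bad[3, ] <- 2
  expect_error(snv(bad), "row\\(s\\): 3")
})

test_that("Savitzky-Golay derivatives are exact on low-degree polynomials", {
  x <- seq_len(151)
  cubic <- 2 - 3 * x + 0.5 * x^2 - 0.01 * x^3
  quad <- 1 + 2 * x - 0.3 * x^2
  ramp <- 5 - 0.7 * x
  X <- rbind(cubic, quad, ramp, rep(4, 151))
  d1 <- savgolDerivative(X, 1)
  d2 <- savgolDerivative(X, 2)
  expect_equal(dim(d1), dim(X)) # full length kept, edges included
  expect_equal(d1[1, ], -3 + x - 0.03 * x^2, tolerance = 1e-8)
  expect_equal(d2[2, ], rep(-0.6, 151), tolerance = 1e-8)
  expect_equal(d1[3, ], rep(-0.7, 151), tolerance = 1e-10)
  expect_equal(d2[4, ], rep(0, 151), tolerance = 1e-12)
  expect_error(savgolDerivative(X[, 1:10], 1), "shorter")
})

test_that("SG first derivative tracks finite differences on a band", {
  g <- seq(4000, 7000, 20)
  y <- simulatePureSpectrum(cbind(5500, 300, 1), g)
  d1 <- savgolDerivative(matrix(y, 1), 1)[1, ]
  fd <- c(NA, diff(y, lag = 2) / 2, NA) # central differences, per point
  interior <- 30:120
  expect_equal(d1[interior], fd[interior], tolerance = 0.01)
})

test_that("mean centering stores training means and never uses test data", {
  set.seed(2)
  X <- matrix(rnorm(80), 8)
  Xc <- meanCenter(X)
  expect_equal(colMeans(Xc), rep(0, 10), tolerance = 1e-12)
  mu <- attr(Xc, "columnMeans")
  # a test block with a shifted mean keeps its shift under stored means
  shift <- 3
  Xt <- X[1:4, ] + shift
  Xtc <- meanCenter(Xt, mu)
  expect_equal(colMeans(Xtc) - colMeans(meanCenter(X[1:4, ], mu)),
               rep(shift, 10), tolerance = 1e-10)
  expect_error(meanCenter(X, mu[1:3]), "length")
  one <- meanCenter(X[1, , drop = FALSE])
  expect_equal(as.numeric(one), rep(0, 10))
})

test_that("recipes compose exactly as manual operator chains", {
  ds <- quickDataset(3)
  X <- absorbance(ds)
  # single-step recipe equals the bare operator
  expect_equal(applyPreproc(preprocSpec("mc"), X)$train,
               meanCenter(X), ignore_attr = TRUE)
  # snv -> d2 -> mc equals the hand-written chain
  man <- meanCenter(savgolDerivative(snv(X), 2, 19, 3))
  auto <- applyPreproc(preprocSpec(c("snv", "d2", "mc")), X)
  expect_equal(auto$train, man, ignore_attr = TRUE)
  expect_equal(auto$mcMeans, attr(man, "columnMeans"))
  # the six candidate recipes give six distinct blocks
  blocks <- lapply(strategy1Specs(), function(sp) applyPreproc(sp, X)$train)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(max(abs(blocks[[i]] - blocks[[j]])), 1e-6)
  }
})

test_that("recipe validation rejects ill-formed step lists", {
  expect_error(preprocSpec(c("mc", "snv")), "last")
  expect_error(preprocSpec(c("d1", "d1")), "at most once")
  expect_error(preprocSpec("snv", sgWindow = 18), "odd")
  expect_error(preprocSpec("foo"), "unknown")
})
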