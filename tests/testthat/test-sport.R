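test_that("orthogonalization removes exactly the score span", {
  set.seed(20)
  X <- matrix(rnorm(60), 12)
  expect_identical(orthogonalizeBlock(X, NULL), X)
  expect_identical(orthogonalizeBlock(X, matrix(0, 12, 0)), X)
  T <- matrix(rnorm(60), 12, 5)
  Xin <- T %*% matrix(rnorm(20), 5, 4) # columns inside span(T)
  expect_lt(max(abs(orthogonalizeBlock(Xin, T))), 1e-8)
  # explicit projector oracle
  P <- T %*% solve(crossprod(T)) %*% t(T)
  expect_equal(orthogonalizeBlock(X, T), X - P %*% X, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(T, orthogonalizeBlock(X, T)))), 1e-8)
  # rank-deficient score matrices are handled via their basis
  Tdef <- cbind(T[, 1], T[, 1], T[, 2])
  expect_equal(orthogonalizeBlock(X, Tdef),
               orthogonalizeBlock(X, T[, 1:2]), tolerance = 1e-9)
  expect_error(orthogonalizeBlock(X, T[1:5, ]), "rows")
})

test_that("a single-block chain reduces exactly to plain PLS", {
  set.seed(21)
  X <- matrix(rnorm(200), 20)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(20)
  sm <- fitSport(list(X), y, 3L)
  pm <- fitPls(X, y, 3L)
  expect_equal(predict(sm, list(X)), predict(pm, X), tolerance = 1e-10)
  expect_equal(sm@fitted, predict(pm, X), tolerance = 1e-10)
  # VIP of the single-entry chain equals plain PLS VIP
  expect_equal(vip(sm)$scores, vip(pm)$scores, tolerance = 1e-10)
})

test_that("a duplicated block contributes nothing once its rank is spent", {
  set.seed(22)
  X <- matrix(rnorm(200), 20)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(20)
  # block 1 exhausts the 10-dimensional row space; the duplicate block is
  # then fully inside the accumulated score span and adds no components
  one <- fitSport(list(X), y, 10L)
  two <- fitSport(list(X, X), y, c(10L, 3L))
  expect_equal(two@entries[[2]]$nLv, 0L)
  expect_equal(two@fitted, one@fitted, tolerance = 1e-6)
  expect_equal(predict(two, list(X, X)), predict(one, list(X)),
               tolerance = 1e-6)
  # below full rank the duplicate legitimately keeps extracting: the chain
  # with (4, 3) over two copies matches a single 7-component fit
  seven <- fitSport(list(X, X), y, c(4L, 3L))
  expect_equal(seven@fitted, fitPls(X, y, 7)@scores %*%
                 fitPls(X, y, 7)@yLoadings + mean(y),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("multi-block chains keep cross-entry scores orthogonal", {
  ds <- quickDataset(23)
  y <- responses(ds)
  X <- absorbance(ds)
  specs <- sportBlockSpecs()[c("mc", "d1", "snv")]
  pp <- lapply(specs, function(sp) applyPreproc(sp, X))
  model <- fitSport(lapply(pp, `[[`, "train"), y, c(1L, 7L, 6L),
                    specs = specs, wavenumbers = wavenumbers(ds),
                    mcMeans = lapply(pp, `[[`, "mcMeans"))
  expect_true(validObject(model)) # validity enforces the orthogonality
  Tall <- do.call(cbind, lapply(Filter(function(e) e$nLv > 0, model@entries),
                                function(e) e$pls@scores))
  G <- crossprod(Tall)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  # training rows predicted through the stored-preprocessing path
  expect_equal(predict(model, ds@block), model@fitted, tolerance = 1e-6)
  expect_error(predict(model, spectraBlock(wavenumbers(ds) + 5, X)), "axis")
})

test_that("zero-LV blocks leave predictions identical", {
  set.seed(24)
  X <- matrix(rnorm(200), 20)
  B <- snv(X)
  y <- as.numeric(X %*% rnorm(10)) + rnorm(20)
  with0 <- fitSport(list(X, B), y, c(3L, 0L))
  without <- fitSport(list(X), y, 3L)
  expect_identical(predict(with0, list(X, B)), predict(without, list(X)))
  mid0 <- fitSport(list(X, B, X), y, c(2L, 0L, 2L))
  no0 <- fitSport(list(X, X), y, c(2L, 2L))
  expect_identical(predict(mid0, list(X, B, X)), predict(no0, list(X, X)))
  expect_error(fitSport(list(X, B), y, c(0L, 0L)), "positive")
})

test_that("noise-free synthetic test samples are predicted almost exactly", {
  ds <- simulateNirDataset(mixtureDesign(), cleanConfig(noiseSd = 1e-8))
  split <- rankedSplit(ds)
  cal <- ds[split$calibration]
  tst <- ds[split$test]
  specs <- sportBlockSpecs()[c("mc", "snv")]
  pp <- lapply(specs, function(sp) applyPreproc(sp, absorbance(cal)))
  model <- fitSport(lapply(pp, `[[`, "train"), responses(cal), c(2L, 1L),
                    specs = specs, wavenumbers = wavenumbers(ds),
                    mcMeans = lapply(pp, `[[`, "mcMeans"))
  met <- regressionMetrics(responses(tst), predict(model, tst@block))
  expect_gt(met$r2, 0.99)
})

test_that("multi-block VIP is normalized and flags the seeded band regions", {
  # well-separated narrow bands give unambiguous ground truth for where
  # the response information lives
  mk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "width", "amplitude")
    m
  }
  lib <- list(
    api = mk(6500, 40, 4, 5300, 35, 5, 4500, 30, 3),
    starch = mk(6900, 60, 0.9, 5100, 50, 1),
    lactose = mk(6750, 55, 0.8, 4900, 45, 1.1)
  )
  ds <- quickDataset(25, bandLibrary = lib)
  split <- rankedSplit(ds)
  cal <- ds[split$calibration]
  specs <- sportBlockSpecs()[c("d1", "d2")]
  pp <- lapply(specs, function(sp) applyPreproc(sp, absorbance(cal)))
  model <- fitSport(lapply(pp, `[[`, "train"), responses(cal), c(5L, 3L),
                    specs = specs, wavenumbers = wavenumbers(ds),
                    mcMeans = lapply(pp, `[[`, "mcMeans"))
  v <- vip(model)
  expect_equal(mean(v$scores^2), 1, tolerance = 1e-10)
  expect_lt(mean(v$flagged), 0.5) # mean-square-1 bounds the flagged share
  wn <- wavenumbers(ds)
  centers <- unlist(lapply(lib, function(m) m[, "center"]))
  nearBand <- vapply(wn[v$flagged], function(w) any(abs(centers - w) <= 150),
                     TRUE)
  expect_gte(mean(nearBand), 0.8)
})

test_that("order enumeration covers all permutations", {
  expect_length(enumerateOrders(sportBlockSpecs()["mc"]), 1L)
  expect_length(enumerateOrders(sportBlockSpecs()[1:3]), 6L)
  o4 <- enumerateOrders(sportBlockSpecs())
  expect_length(o4, 24L)
  expect_equal(unique(vapply(o4, paste, "", collapse = ",")) |> length(), 24L)
  expect_error(enumerateOrders(list()), "1 to 4")
})

test_that("SPORT models serialize to JSON and back", {
  ds <- quickDataset(26)
  specs <- sportBlockSpecs()[c("mc", "snv")]
  X <- absorbance(ds)
  pp <- lapply(specs, function(sp) applyPreproc(sp, X))
  model <- fitSport(lapply(pp, `[[`, "train"), responses(ds), c(2L, 3L),
                    specs = specs, wavenumbers = wavenumbers(ds),
                    mcMeans = lapply(pp, `[[`, "mcMeans"))
  f <- withr::local_tempfile(fileext = ".json")
  writeSportModel(model, f)
  m2 <- readSportModel(f)
  expect_equal(predict(m2, ds@block), predict(model, ds@block),
               tolerance = 1e-10)
})
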