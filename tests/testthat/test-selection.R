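test_that("the ranked split reproduces the study cardinalities", {
  ds <- quickDataset(30)
  sp <- rankedSplit(ds)
  expect_length(sp$test, 10L)
  expect_length(sp$calibration, 44L)
  expect_length(intersect(sp$calibration, sp$test), 0L)
  # test mixtures are exactly the concentration ranks 5, 10, 15, 20, 25
  d <- mixtureDesign()
  ranked <- d$sample_id[order(d$api_mgkg, d$sample_id)]
  expect_setequal(sp$testSamples, as.character(ranked[c(5, 10, 15, 20, 25)]))
  # replicates never straddle the split
  sid <- sampleIds(ds)
  expect_length(intersect(sid[sp$calibration], sid[sp$test]), 0L)
})

test_that("fold assignment partitions samples evenly and by rank", {
  ds <- quickDataset(31)
  cal <- ds[rankedSplit(ds)$calibration]
  fold <- sportnir:::.foldAssignment(sampleIds(cal), responses(cal), 7L)
  perSample <- tapply(fold, sampleIds(cal), unique)
  expect_true(all(lengths(perSample) == 1L)) # replicates share folds
  sizes <- table(unlist(perSample))
  expect_lte(diff(range(sizes)), 1L)
  expect_error(sportnir:::.foldAssignment(sampleIds(cal), responses(cal), 1L),
               ">= 2")
})

test_that("kfoldCv matches a hand-rolled fold loop", {
  ds <- quickDataset(32)
  cal <- ds[rankedSplit(ds)$calibration]
  fitPredict <- function(Xtr, ytr, Xte) predict(fitPls(Xtr, ytr, 3), Xte)
  got <- kfoldCv(cal, fitPredict, k = 7)
  expect_true(all(!is.na(got$predictions)))
  # oracle: explicit loop with the same fold assignment
  y <- responses(cal)
  X <- absorbance(cal)
  fold <- sportnir:::.foldAssignment(sampleIds(cal), y, 7L)
  pred <- rep(NA_real_, length(y))
  for (f in 1:7) {
    m <- fitPls(X[fold != f, ], y[fold != f], 3)
    pred[fold == f] <- predict(m, X[fold == f, , drop = FALSE])
  }
  expect_equal(got$predictions, pred)
  expect_equal(got$rmsecv, sqrt(mean((pred - y)^2)))
  expect_equal(got$r2cv, 1 - sum((pred - y)^2) / sum((y - mean(y))^2))
})

test_that("cross-validation is invariant to row order and near-exact on clean data", {
  ds <- simulateNirDataset(mixtureDesign(), cleanConfig(noiseSd = 1e-7))
  cal <- ds[rankedSplit(ds)$calibration]
  sel <- selectLv(cal, strategy1Specs()$raw, lvMax = 4)
  expect_lt(sel$rmsecv, 1) # mg/kg; essentially exact
  expect_gt(sel$r2cv, 0.999)
  # permuting the rows changes nothing (folds are rank-based)
  set.seed(99)
  perm <- sample(seq_len(nSpectra(cal)))
  selP <- selectLv(cal[perm], strategy1Specs()$raw, lvMax = 4)
  expect_equal(selP$cv$rmsecv, sel$cv$rmsecv, tolerance = 1e-9)
})

test_that("LV choice follows the 2%-of-minimum parsimony rule", {
  ds <- quickDataset(33)
  cal <- ds[rankedSplit(ds)$calibration]
  sel <- selectLv(cal, strategy1Specs()$d1)
  cv <- sel$cv
  eligible <- cv$lv[cv$rmsecv <= 1.02 * min(cv$rmsecv)]
  expect_equal(sel$nLv, min(eligible))
  # flat error curve: one latent variable is enough and is chosen
  flat <- selectLv(ds, preprocSpec("mc"), lvMax = 5)
  expect_true(flat$nLv == min(flat$cv$lv[flat$cv$rmsecv <=
                                           1.02 * min(flat$cv$rmsecv)]))
})

test_that("the SPORT search reduces to single-block selection", {
  ds <- quickDataset(34)
  cal <- ds[rankedSplit(ds)$calibration]
  one <- selectLv(cal, sportBlockSpecs()$d1)
  viaSearch <- selectSport(cal, sportBlockSpecs()["d1"], lvMax = 10)
  expect_equal(viaSearch$lvs, one$nLv)
  expect_equal(viaSearch$rmsecv, one$rmsecv, tolerance = 1e-8)
  expect_equal(viaSearch$r2cv, one$r2cv, tolerance = 1e-8)
})

test_that("the search grid has the expected size and caching is lossless", {
  ds <- quickDataset(35)
  cal <- ds[rankedSplit(ds)$calibration]
  specs3 <- sportBlockSpecs()[c("mc", "snv", "d1")]
  lv3 <- selectSport(cal, specs3, lvMax = 3)
  expect_length(lv3$rmsecvAll, factorial(3) * 4^3)
  # prefix caching is bit-identical to the from-scratch recomputation
  lv3un <- selectSport(cal, specs3, lvMax = 3, cached = FALSE)
  expect_identical(lv3$rmsecvAll, lv3un$rmsecvAll)
  # row-space compression changes nothing numerically
  lv3full <- selectSport(cal, specs3, lvMax = 3, compress = FALSE)
  expect_equal(lv3$rmsecvAll, lv3full$rmsecvAll, tolerance = 1e-8)
})

test_that("the search agrees with an explicit fitSport fold loop", {
  ds <- quickDataset(36)
  cal <- ds[rankedSplit(ds)$calibration]
  specs <- sportBlockSpecs()[c("snv", "d2")]
  got <- selectSport(cal, specs, lvMax = 2, k = 4)
  y <- responses(cal)
  X <- absorbance(cal)
  fold <- sportnir:::.foldAssignment(sampleIds(cal), y, 4L)
  oracle <- function(orderIdx, lvs) {
    pred <- rep(NA_real_, length(y))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      pp <- lapply(specs[orderIdx], function(sp) {
        applyPreproc(sp, X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      })
      m <- fitSport(lapply(pp, `[[`, "train"), y[tr], lvs)
      pred[!tr] <- predict(m, lapply(pp, `[[`, "test"))
    }
    sqrt(mean((pred - y)^2))
  }
  # a handful of configurations across both orderings
  expect_equal(got$rmsecvAll[["snv>d2:1,2"]], oracle(c(1, 2), c(1L, 2L)),
               tolerance = 1e-7)
  expect_equal(got$rmsecvAll[["snv>d2:2,0"]], oracle(c(1, 2), c(2L, 0L)),
               tolerance = 1e-7)
  expect_equal(got$rmsecvAll[["d2>snv:2,1"]], oracle(c(2, 1), c(2L, 1L)),
               tolerance = 1e-7)
  # the chosen configuration obeys the parsimony rule over the whole grid
  finite <- is.finite(got$rmsecvAll)
  expect_lte(got$rmsecv, 1.02 * min(got$rmsecvAll[finite]))
})

test_that("the single-block pipeline reports all six models", {
  ds <- quickDataset(37)
  sp <- rankedSplit(ds)
  rep1 <- runStrategy1(ds, sp, lvMax = 6)
  expect_equal(nrow(rep1), 6L)
  expect_setequal(rep1$model, names(strategy1Specs()))
  expect_true(all(rep1$rmsecv >= 0 & rep1$rmsep >= 0))
  expect_true(all(rep1$nLv >= 1 & rep1$nLv <= 6))
  # noise-free limit: every pretreatment predicts essentially exactly
  clean <- simulateNirDataset(mixtureDesign(), cleanConfig(noiseSd = 1e-7))
  repC <- runStrategy1(clean, rankedSplit(clean), lvMax = 4)
  # mg/kg on a 500-6200 scale: derivative/raw models are essentially exact;
  # SNV's per-spectrum rescaling bends the linearity slightly but stays
  # under 1% of the response range
  expect_true(all(repC$rmsep < 60))
  expect_true(all(repC$rmsep[repC$model %in% c("raw", "d1", "d2")] < 1))
})

test_that("the multi-block pipeline beats its own best single candidate block", {
  ds <- quickDataset(38)
  sp <- rankedSplit(ds)
  card <- runStrategy2(ds, sp, lvMax = 6)
  expect_true(validObject(card$model))
  expect_lt(mean(card$vip$flagged), 0.5)
  expect_equal(mean(card$vip$scores^2), 1, tolerance = 1e-10)
  # reduction property: the grid contains each candidate block alone, so
  # the selected chain cannot be worse than the best single candidate
  # block by more than the 2% parsimony slack
  cal <- ds[sp$calibration]
  singles <- vapply(sportBlockSpecs(), function(b) {
    selectLv(cal, b, lvMax = 6)$rmsecv
  }, 0)
  expect_lte(card$rmsecv, 1.05 * min(singles))
  # the refitted winner reproduces the search's cross-validated choice
  expect_length(card$lvs, 4L)
  expect_gt(sum(card$lvs), 0)
})
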