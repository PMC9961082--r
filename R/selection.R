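#' Concentration-ranked calibration/test split
#'
#' Sorts the distinct samples by ascending API concentration (ties broken
#' by sample id) and sends every `everyN`-th sample (ranks `everyN`,
#' `2 everyN`, ...) to the test set together with all of its replicate
#' spectra; the remainder form the calibration set. With the built-in
#' 27-mixture design and 2 replicates this yields 10 test spectra and 44
#' calibration spectra.
#'
#' @param dataset a [NirDataset-class].
#' @param everyN test-set stride over the concentration ranking (default 5).
#' @return list with `calibration` and `test` (row indices into the
#'   dataset), `testSamples` (ids), and `rule` (descriptor string).
#' @export
rankedSplit <- function(dataset, everyN = 5L) {
  stopifnot(is(dataset, "NirDataset"))
  sid <- sampleIds(dataset)
  y <- responses(dataset)
  first <- !duplicated(sid)
  samp <- data.frame(id = sid[first], conc = y[first])
  if (nrow(samp) < everyN) stop("need at least ", everyN, " distinct samples")
  samp <- samp[order(samp$conc, samp$id), ]
  ranks <- seq_len(nrow(samp))
  testIds <- samp$id[ranks %% everyN == 0L]
  testRows <- which(sid %in% testIds)
  calRows <- setdiff(seq_along(sid), testRows)
  stopifnot(length(intersect(calRows, testRows)) == 0L,
            length(calRows) + length(testRows) == length(sid))
  list(calibration = calRows, test = testRows, testSamples = testIds,
       rule = sprintf("every %d-th sample by ascending concentration", everyN))
}

# Per-row fold assignment: contiguous blocks over the distinct samples
# sorted by ascending concentration (ties by id); replicates follow their
# sample. Deterministic - no RNG involved.
.foldAssignment <- function(sampleIds, conc, k) {
  first <- !duplicated(sampleIds)
  samp <- data.frame(id = sampleIds[first], conc = conc[first])
  nSamp <- nrow(samp)
  if (k < 2L) stop("k must be >= 2")
  if (k > nSamp) stop("k exceeds the number of distinct samples")
  samp <- samp[order(samp$conc, samp$id), ]
  sizes <- rep(nSamp %/% k, k) + c(rep(1L, nSamp %% k), rep(0L, k - nSamp %% k))
  sampleFold <- rep(seq_len(k), sizes)
  sampleFold[match(sampleIds, samp$id)]
}

#' Sample-grouped k-fold cross-validation
#'
#' Folds are contiguous blocks over the distinct samples sorted by
#' ascending response; replicate spectra always share their sample's fold.
#' Every sample is predicted exactly once. `RMSECV` is computed over all
#' held-out predictions and `R2CV = 1 - PRESS/TSS` with the total sum of
#' squares about the full calibration mean.
#'
#' @param dataset a [NirDataset-class] (the calibration set).
#' @param fitPredict function `(Xtrain, yTrain, Xtest) -> predictions`.
#' @param k number of folds (default 7).
#' @return list with `predictions` (aligned to dataset rows), `fold`
#'   (per-row fold index), `rmsecv`, `r2cv`.
#' @export
kfoldCv <- function(dataset, fitPredict, k = 7L) {
  stopifnot(is(dataset, "NirDataset"))
  X <- absorbance(dataset)
  y <- responses(dataset)
  fold <- .foldAssignment(sampleIds(dataset), y, k)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    hold <- fold == f
    pred[hold] <- fitPredict(X[!hold, , drop = FALSE], y[!hold],
                             X[hold, , drop = FALSE])
  }
  press <- sum((pred - y)^2)
  tss <- sum((y - mean(y))^2)
  list(predictions = pred, fold = fold,
       rmsecv = sqrt(press / length(y)), r2cv = 1 - press / tss)
}

# PRESS per LV count (1..lvMax) for one preprocessed predictor matrix,
# from one NIPALS fit per fold (truncations are free).
.cvPressPerLv <- function(X, y, fold, lvMax) {
  press <- numeric(lvMax)
  for (f in sort(unique(fold))) {
    hold <- fold == f
    m <- fitPls(X[!hold, , drop = FALSE], y[!hold], lvMax)
    pp <- .plsPredictPerLv(m, X[hold, , drop = FALSE])
    press <- press + colSums((pp - y[hold])^2)
  }
  press
}

# Parsimony rule: smallest complexity whose RMSECV is within (1 + slack)
# of the minimum.
.parsimonyPick <- function(complexity, rmsecv, slack = 0.02) {
  eligible <- which(rmsecv <= (1 + slack) * min(rmsecv))
  eligible[order(complexity[eligible], rmsecv[eligible])][1L]
}

#' Select the latent-variable count for a single-block model
#'
#' Cross-validates PLS models with 1 to `lvMax` latent variables on the
#' given pretreatment and picks the smallest count whose RMSECV is within
#' 2% of the minimum (a parsimony-vs-error compromise).
#'
#' @param dataset calibration [NirDataset-class].
#' @param spec a [PreprocSpec-class].
#' @param lvMax largest latent-variable count searched (default 10).
#' @param k folds (default 7).
#' @param slack parsimony tolerance on RMSECV (default 0.02).
#' @return list with `nLv` (chosen), `rmsecv`/`r2cv` at the choice, and
#'   `cv` (data.frame over the grid: `lv`, `rmsecv`, `r2cv`).
#' @export
selectLv <- function(dataset, spec, lvMax = 10L, k = 7L, slack = 0.02) {
  stopifnot(is(dataset, "NirDataset"))
  y <- responses(dataset)
  Xp <- applyPreproc(spec, absorbance(dataset))$train
  fold <- .foldAssignment(sampleIds(dataset), y, k)
  press <- .cvPressPerLv(Xp, y, fold, lvMax)
  tss <- sum((y - mean(y))^2)
  cv <- data.frame(lv = seq_len(lvMax), rmsecv = sqrt(press / length(y)),
                   r2cv = 1 - press / tss)
  pick <- .parsimonyPick(cv$lv, cv$rmsecv, slack)
  list(nLv = cv$lv[pick], rmsecv = cv$rmsecv[pick], r2cv = cv$r2cv[pick],
       cv = cv)
}

# Orthonormal row-space compression of one fold's block pair: PLS scores,
# fitted values and held-out predictions are invariant under right-
# multiplication by an orthonormal basis of the training row space, so the
# grid search runs on n x r coordinates instead of n x p.
.compressPair <- function(Xtr, Xte) {
  sv <- svd(Xtr, nu = 0)
  keep <- sv$d > max(sv$d) * 1e-12
  V <- sv$v[, keep, drop = FALSE]
  list(train = Xtr %*% V, test = Xte %*% V)
}

#' Search block orders and latent-variable vectors for the multi-block model
#'
#' Exhaustive cross-validated search for the sequential orthogonalized
#' multi-block model: every ordering of the candidate blocks times every
#' latent-variable vector in `{0..lvMax}` per block (a block with 0 latent
#' variables is skipped, so all subsets of the candidates are covered).
#' Within one fold, configurations sharing a chain prefix reuse its fitted
#' state (prefix caching), and each block is compressed onto an orthonormal
#' basis of its training row space, which leaves all PLS computations
#' unchanged. The choice applies the same 2%-of-minimum parsimony rule on
#' the total number of latent variables; remaining ties go to the lower
#' RMSECV, then to the earlier ordering.
#'
#' @param dataset calibration [NirDataset-class].
#' @param blockSpecs named list of candidate [PreprocSpec-class] blocks
#'   (default [sportBlockSpecs()], at most 4).
#' @param lvMax largest per-block latent-variable count (default 10).
#' @param k folds (default 7).
#' @param slack parsimony tolerance on RMSECV (default 0.02).
#' @param compress use row-space compression (default `TRUE`).
#' @param cached reuse shared chain prefixes (default `TRUE`; `FALSE`
#'   recomputes every configuration from scratch and is only practical on
#'   small grids).
#' @return list with `order` (block indices), `orderNames`, `lvs` (per
#'   position), `rmsecv`, `r2cv`, `perOrdering` (data.frame with the best
#'   configuration of every ordering) and `rmsecvAll` (named vector over
#'   the full grid, orderings x LV vectors).
#' @export
selectSport <- function(dataset, blockSpecs = sportBlockSpecs(),
                        lvMax = 10L, k = 7L, slack = 0.02,
                        compress = TRUE, cached = TRUE) {
  stopifnot(is(dataset, "NirDataset"))
  K <- length(blockSpecs)
  if (K < 1L || K > 4L) stop("1 to 4 candidate blocks are supported")
  y <- responses(dataset)
  n <- length(y)
  Xraw <- absorbance(dataset)
  # row-wise pretreatments once; fold-level centering happens inside the
  # sub-fits (equivalent to mean centering learned per fold)
  rowwise <- lapply(blockSpecs, function(sp) {
    st <- setdiff(sp@steps, "mc")
    if (!length(st)) return(Xraw)
    applyPreproc(preprocSpec(st, sp@sgWindow, sp@sgPolyorder), Xraw)$train
  })
  fold <- .foldAssignment(sampleIds(dataset), y, k)
  S <- lvMax + 1L
  press <- NULL
  for (f in sort(unique(fold))) {
    hold <- fold == f
    tr <- list()
    te <- list()
    for (b in seq_len(K)) {
      Xtr <- rowwise[[b]][!hold, , drop = FALSE]
      Xte <- rowwise[[b]][hold, , drop = FALSE]
      if (compress) {
        cp <- .compressPair(Xtr, Xte)
        Xtr <- cp$train
        Xte <- cp$test
      }
      tr[[b]] <- Xtr
      te[[b]] <- Xte
    }
    pf <- .sportCvPress(tr, te, y[!hold], y[hold], as.integer(lvMax), cached)
    press <- if (is.null(press)) pf else press + pf
  }
  orders <- enumerateOrders(blockSpecs)
  nPerm <- length(orders)
  nCfg <- nPerm * S^K
  stopifnot(length(press) == nCfg)
  # decode config ids: ordering index and per-position LV counts
  cfg <- seq_len(nCfg) - 1L
  permIdx <- cfg %/% S^K
  lvMat <- matrix(0L, nCfg, K)
  rest <- cfg %% S^K
  for (j in K:1) {
    lvMat[, j] <- rest %% S
    rest <- rest %/% S
  }
  totalLv <- rowSums(lvMat)
  rmsecv <- sqrt(press / n)
  rmsecv[totalLv == 0L] <- Inf # no latent variables at all: not a model
  tss <- sum((y - mean(y))^2)
  orderName <- vapply(orders, function(o) {
    nm <- names(o)
    if (is.null(nm)) paste(o, collapse = ">") else paste(nm, collapse = ">")
  }, "")
  pickGlobal <- {
    eligible <- which(rmsecv <= (1 + slack) * min(rmsecv))
    eligible[order(totalLv[eligible], rmsecv[eligible],
                   permIdx[eligible])][1L]
  }
  perOrdering <- do.call(rbind, lapply(seq_len(nPerm), function(ip) {
    rows <- which(permIdx == ip - 1L)
    rp <- rmsecv[rows]
    el <- rows[rp <= (1 + slack) * min(rp)]
    best <- el[order(totalLv[el], rmsecv[el])][1L]
    data.frame(ordering = orderName[ip],
               lvs = paste(lvMat[best, ], collapse = ","),
               totalLv = totalLv[best], rmsecv = rmsecv[best],
               r2cv = 1 - press[best] / tss)
  }))
  best <- pickGlobal
  names(rmsecv) <- paste0(orderName[permIdx + 1L], ":",
                          apply(lvMat, 1L, paste, collapse = ","))
  list(
    order = unname(orders[[permIdx[best] + 1L]]),
    orderNames = names(orders[[permIdx[best] + 1L]]),
    lvs = lvMat[best, ],
    rmsecv = rmsecv[[best]],
    r2cv = 1 - press[best] / tss,
    perOrdering = perOrdering,
    rmsecvAll = rmsecv
  )
}

#' Run the single-block calibration pipeline
#'
#' For each candidate pretreatment: preprocess (training-learned centering),
#' pick the latent-variable count by sample-grouped cross-validation on the
#' calibration set, refit on the full calibration set, and predict the test
#' set. Test rows are verified to be disjoint from calibration rows and are
#' never touched before the final prediction.
#'
#' @param dataset a [NirDataset-class].
#' @param split a split from [rankedSplit()].
#' @param specs named list of [PreprocSpec-class] (default
#'   [strategy1Specs()]).
#' @param lvMax,k,slack see [selectLv()].
#' @return data.frame with one row per pretreatment: `model`,
#'   `preprocessing`, `nLv`, `rmsecv`, `r2cv`, `rmsep`, `bias`, `r2pred`
#'   (test-mean convention) and `r2pred_cal` (calibration-mean convention).
#' @export
runStrategy1 <- function(dataset, split, specs = strategy1Specs(),
                         lvMax = 10L, k = 7L, slack = 0.02) {
  stopifnot(is(dataset, "NirDataset"))
  stopifnot(length(intersect(split$calibration, split$test)) == 0L)
  cal <- dataset[split$calibration]
  tst <- dataset[split$test]
  yCal <- responses(cal)
  yTst <- responses(tst)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sel <- selectLv(cal, sp, lvMax = lvMax, k = k, slack = slack)
    pp <- applyPreproc(sp, absorbance(cal), absorbance(tst))
    fit <- fitPls(pp$train, yCal, sel$nLv)
    pred <- predict(fit, pp$test)
    met <- regressionMetrics(yTst, pred)
    metCal <- regressionMetrics(yTst, pred, "calibration-mean", mean(yCal))
    data.frame(model = names(specs)[i], preprocessing = sp@label,
               nLv = sel$nLv, rmsecv = sel$rmsecv, r2cv = sel$r2cv,
               rmsep = met$rmse, bias = met$bias, r2pred = met$r2,
               r2pred_cal = metCal$r2)
  })
  do.call(rbind, rows)
}

#' Run the multi-block (SPORT) calibration pipeline
#'
#' Searches block orders and latent-variable vectors by cross-validation on
#' the calibration set ([selectSport()]), refits the winning chain on the
#' full calibration set, predicts the test set from the raw spectra (stored
#' preprocessing recipes and training statistics), and computes VIP scores
#' on the shared wavenumber axis.
#'
#' @param dataset a [NirDataset-class].
#' @param split a split from [rankedSplit()].
#' @param blockSpecs candidate blocks (default [sportBlockSpecs()]).
#' @param lvMax,k,slack,compress see [selectSport()].
#' @return list (model card) with `order`, `orderNames`, `lvs`, `rmsecv`,
#'   `r2cv`, `rmsep`, `bias`, `r2pred`, `r2pred_cal`, `vip` (scores,
#'   threshold, flagged), `model` (the refitted [SportModel-class]),
#'   `perOrdering`, and `predictions`/`observed` for the test set.
#' @export
runStrategy2 <- function(dataset, split, blockSpecs = sportBlockSpecs(),
                         lvMax = 10L, k = 7L, slack = 0.02,
                         compress = TRUE) {
  stopifnot(is(dataset, "NirDataset"))
  stopifnot(length(intersect(split$calibration, split$test)) == 0L)
  cal <- dataset[split$calibration]
  tst <- dataset[split$test]
  yCal <- responses(cal)
  yTst <- responses(tst)
  sel <- selectSport(cal, blockSpecs, lvMax = lvMax, k = k, slack = slack,
                     compress = compress)
  useOrder <- sel$order
  useLvs <- sel$lvs
  keep <- useLvs > 0L
  specsUsed <- blockSpecs[useOrder]
  pp <- lapply(specsUsed, function(sp) applyPreproc(sp, absorbance(cal)))
  model <- fitSport(
    blocks = lapply(pp, `[[`, "train"),
    y = yCal, lvs = useLvs, specs = specsUsed,
    wavenumbers = wavenumbers(dataset),
    mcMeans = lapply(pp, `[[`, "mcMeans")
  )
  pred <- predict(model, tst@block)
  met <- regressionMetrics(yTst, pred)
  metCal <- regressionMetrics(yTst, pred, "calibration-mean", mean(yCal))
  list(
    order = useOrder, orderNames = sel$orderNames, lvs = useLvs,
    activeChain = paste(sprintf("%s(%d)", sel$orderNames[keep], useLvs[keep]),
                        collapse = " -> "),
    rmsecv = sel$rmsecv, r2cv = sel$r2cv,
    rmsep = met$rmse, bias = met$bias, r2pred = met$r2,
    r2pred_cal = metCal$r2,
    vip = vip(model), model = model, perOrdering = sel$perOrdering,
    predictions = pred, observed = yTst
  )
}
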