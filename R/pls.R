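#' Fit a single-response PLS regression (NIPALS PLS1)
#'
#' NIPALS algorithm with X-deflation: for each latent variable the weight
#' vector is `w = X'y / ||X'y||`, scores `t = X w`, X-loading
#' `p = X't / t't`, response loading `q = y't / t't`, followed by the rank-1
#' deflation `X <- X - t p'`. X and y are centered internally; no scaling
#' is applied. The sign of each weight vector is fixed by forcing its
#' largest-magnitude element positive, making the fit fully deterministic.
#' The regression vector is `b = W (P'W)^{-1} q`.
#'
#' @param X predictor matrix, samples x variables.
#' @param y response vector, one value per row of `X`.
#' @param nLv number of latent variables (>= 1, at most
#'   `min(nrow(X) - 1, ncol(X))` and no more than the rank of the centered
#'   data supports).
#' @return a [PlsModel-class].
#' @examples
#' X <- matrix(rnorm(40), 10)
#' m <- fitPls(X, X %*% c(1, -1, 0, 2), nLv = 4)
#' max(abs(predict(m, X) - X %*% c(1, -1, 0, 2)))
#' @export
fitPls <- function(X, y, nLv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  nLv <- as.integer(nLv)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (nLv < 1L) stop("nLv must be >= 1")
  if (nLv > min(n - 1L, p)) {
    stop(sprintf("nLv = %d exceeds min(samples - 1, variables) = %d",
                 nLv, min(n - 1L, p)))
  }
  if (stats::var(y) == 0) stop("response has zero variance")
  .nipalsPls1(X, y, nLv, strict = TRUE)
}

# NIPALS core. strict = TRUE errors when nLv exceeds the data rank;
# strict = FALSE stops extracting instead (returns NULL when not even one
# component is available) - used inside multi-block chains, where later
# blocks may be fully explained by earlier scores.
.nipalsPls1 <- function(X, y, nLv, strict = TRUE) {
  n <- nrow(X)
  p <- ncol(X)
  xMeans <- colMeans(X)
  yMean <- mean(y)
  Xc <- X - rep(xMeans, each = n)
  yc <- y - yMean
  tol <- 1e-12 * max(abs(Xc), 1)
  W <- matrix(0, p, nLv)
  P <- matrix(0, p, nLv)
  Tm <- matrix(0, n, nLv)
  q <- numeric(nLv)
  Xd <- Xc
  aEff <- 0L
  for (a in seq_len(nLv)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    tt <- if (nw >= tol) Xd %*% (w / nw)
    if (nw < tol || sum(tt^2) < tol^2) {
      if (strict) {
        stop(sprintf(
          "nLv = %d exceeds the rank of the centered data (failed at component %d)",
          nLv, a
        ))
      }
      break
    }
    w <- w / nw
    if (w[which.max(abs(w))] < 0) {
      w <- -w
      tt <- -tt
    }
    t2 <- sum(tt^2)
    pp <- crossprod(Xd, tt) / t2
    q[a] <- sum(yc * tt) / t2
    Xd <- Xd - tt %*% t(pp)
    W[, a] <- w
    P[, a] <- pp
    Tm[, a] <- tt
    aEff <- a
  }
  if (aEff == 0L) return(NULL)
  keep <- seq_len(aEff)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]
  q <- q[keep]
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  new("PlsModel", nLv = aEff, weights = W, loadings = P, yLoadings = q,
      scores = Tm, coefficients = b, xMeans = xMeans, yMean = yMean)
}

#' @rdname fitPls
#' @param object,model a fitted `PlsModel`.
#' @param newdata matrix of new spectra on the model's variables.
#' @export
setMethod("predict", "PlsModel", function(object, newdata) {
  Xn <- .asMatrix(newdata)
  if (ncol(Xn) != length(object@xMeans)) {
    stop(sprintf("newdata has %d variables but the model expects %d",
                 ncol(Xn), length(object@xMeans)))
  }
  as.numeric((Xn - rep(object@xMeans, each = nrow(Xn))) %*%
               object@coefficients) + object@yMean
})

#' @rdname fitPls
#' @export
setMethod("scores", "PlsModel", function(object) object@scores)

#' @rdname fitPls
#' @export
setMethod("coef", "PlsModel", function(object) object@coefficients)

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d LV, %d variables, %d training samples\n",
              object@nLv, nrow(object@weights), nrow(object@scores)))
})

# Score path for new data: returns the n_new x A score matrix computed by
# the sequential w/p projection-deflation chain. Used for prediction per
# truncated LV count and inside the multi-block chain.
.plsNewScores <- function(model, Xnew) {
  Xc <- Xnew - rep(model@xMeans, each = nrow(Xnew))
  A <- model@nLv
  Tn <- matrix(0, nrow(Xnew), A)
  for (a in seq_len(A)) {
    tt <- Xc %*% model@weights[, a]
    Tn[, a] <- tt
    Xc <- Xc - tt %*% t(model@loadings[, a])
  }
  Tn
}

# Predictions of the truncated sub-models 1..A as an n_new x A matrix
# (column a = prediction using the first a latent variables).
.plsPredictPerLv <- function(model, Xnew) {
  Tn <- .plsNewScores(model, Xnew)
  contrib <- Tn * rep(model@yLoadings, each = nrow(Tn))
  model@yMean + t(apply(contrib, 1L, cumsum))
}

#' Regression performance metrics
#'
#' Computes the root-mean-square error, the mean signed error (bias,
#' `mean(predicted - measured)`), the coefficient of determination and the
#' residual vector. The sum-of-squares reference for R^2 is either the mean
#' of `yTrue` itself (`"self"`, the external-validation convention used by
#' default) or a supplied calibration mean (`"calibration-mean"`).
#'
#' @param yTrue measured responses (mg/kg).
#' @param yPred predicted responses.
#' @param sstReference `"self"` or `"calibration-mean"`.
#' @param calibrationMean calibration-set response mean, required for the
#'   `"calibration-mean"` convention.
#' @return list with `rmse`, `bias`, `r2`, `residuals`
#'   (`yPred - yTrue`) and `n`.
#' @examples
#' regressionMetrics(c(0, 1, 2), c(0, 2, 2))
#' @export
regressionMetrics <- function(yTrue, yPred,
                              sstReference = c("self", "calibration-mean"),
                              calibrationMean = NULL) {
  sstReference <- match.arg(sstReference)
  yTrue <- as.numeric(yTrue)
  yPred <- as.numeric(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2L) stop("need at least 2 observations")
  res <- yPred - yTrue
  refMean <- if (sstReference == "self") mean(yTrue) else {
    if (is.null(calibrationMean)) {
      stop("calibrationMean is required for the calibration-mean convention")
    }
    calibrationMean
  }
  sst <- sum((yTrue - refMean)^2)
  if (sst == 0) stop("zero total sum of squares")
  list(
    rmse = sqrt(mean(res^2)),
    bias = mean(res),
    r2 = 1 - sum(res^2) / sst,
    residuals = res,
    n = length(yTrue)
  )
}

#' @rdname vip
#' @export
setMethod("vip", "PlsModel", function(object, threshold = 1) {
  ssy <- object@yLoadings^2 * colSums(object@scores^2)
  if (sum(ssy) <= 0) stop("model explains zero response variance")
  # weights have unit norm by construction; normalize defensively anyway
  wn <- sweep(object@weights, 2L, sqrt(colSums(object@weights^2)), "/")
  p <- nrow(wn)
  sc <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  list(scores = sc, threshold = threshold, flagged = sc > threshold)
})

#' Serialize a fitted PLS model to JSON
#'
#' @param model a [PlsModel-class].
#' @param path output file path.
#' @return `path`, invisibly. `readPlsModel()` restores the model.
#' @export
writePlsModel <- function(model, path) {
  stopifnot(is(model, "PlsModel"))
  obj <- list(
    type = "PlsModel", nLv = model@nLv, weights = model@weights,
    loadings = model@loadings, yLoadings = model@yLoadings,
    scores = model@scores, coefficients = model@coefficients,
    xMeans = model@xMeans, yMean = model@yMean
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePlsModel
#' @export
readPlsModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PlsModel", nLv = as.integer(obj$nLv),
      weights = as.matrix(obj$weights), loadings = as.matrix(obj$loadings),
      yLoadings = as.numeric(obj$yLoadings), scores = as.matrix(obj$scores),
      coefficients = as.numeric(obj$coefficients),
      xMeans = as.numeric(obj$xMeans), yMean = as.numeric(obj$yMean))
}
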