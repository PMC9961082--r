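#' Orthogonalize a block against a score matrix
#'
#' Removes from `X` the column-space contribution of the scores `T`,
#' `X_orth = X - T (T'T)^{-1} T' X`, computed through an orthonormal basis
#' of `T`'s column space (QR with rank detection), so rank-deficient score
#' matrices are handled without error. `T' X_orth = 0` up to numerical
#' precision; an empty `T` returns `X` unchanged.
#'
#' @param X matrix, samples x variables.
#' @param T score matrix with the same number of rows (may have 0 columns).
#' @return the orthogonalized matrix.
#' @export
orthogonalizeBlock <- function(X, T) {
  X <- as.matrix(X)
  if (is.null(T) || NCOL(T) == 0L) return(X)
  T <- as.matrix(T)
  if (nrow(T) != nrow(X)) stop("X and T must have the same number of rows")
  qrT <- qr(T)
  r <- qrT$rank
  if (r == 0L) return(X)
  Q <- qr.Q(qrT)[, seq_len(r), drop = FALSE]
  X - Q %*% crossprod(Q, X)
}

#' Fit a SPORT model (sequential orthogonalized multi-block PLS)
#'
#' Fuses an ordered list of differently preprocessed copies of one spectral
#' block into a single calibration. The response mean is absorbed once;
#' then, block by block, the predictor matrix is orthogonalized against the
#' scores accumulated from all earlier blocks, a PLS1 sub-model with the
#' block's latent-variable count is fitted to the current response
#' residuals, its scores join the accumulated score matrix, and the
#' residuals are updated. Blocks assigned 0 latent variables are skipped
#' (and leave predictions unchanged). With a single block the model is
#' exactly plain PLS.
#'
#' @param blocks ordered list of preprocessed predictor matrices sharing
#'   row count and row order.
#' @param y response vector (mg/kg).
#' @param lvs integer vector, latent variables per block (0 allowed; at
#'   least one positive).
#' @param specs optional list of [PreprocSpec-class] per block, stored for
#'   prediction from raw spectra and for reporting.
#' @param wavenumbers optional shared axis, stored for VIP reporting.
#' @param mcMeans optional list of per-block stored training column means
#'   (from [applyPreproc()]), used when predicting from raw spectra.
#' @return a [SportModel-class].
#' @export
fitSport <- function(blocks, y, lvs, specs = NULL, wavenumbers = numeric(),
                     mcMeans = NULL) {
  if (!is.list(blocks) || !length(blocks)) stop("blocks must be a non-empty list")
  blocks <- lapply(blocks, as.matrix)
  n <- nrow(blocks[[1L]])
  if (any(vapply(blocks, nrow, 0L) != n)) {
    stop("all blocks must have the same number of rows")
  }
  y <- as.numeric(y)
  if (length(y) != n) stop("response length must match the block rows")
  lvs <- as.integer(lvs)
  if (length(lvs) != length(blocks)) stop("one LV count per block is required")
  if (any(lvs < 0L)) stop("LV counts must be >= 0")
  if (all(lvs == 0L)) stop("at least one block must have a positive LV count")
  yMean <- mean(y)
  resid <- y - yMean
  Tacc <- matrix(0, n, 0L)
  entries <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    spec <- if (!is.null(specs)) specs[[k]]
    mcm <- if (!is.null(mcMeans)) mcMeans[[k]]
    if (lvs[k] == 0L) {
      entries[[k]] <- list(spec = spec, nLv = 0L, pls = NULL,
                           scoreMap = NULL, mcMeans = mcm)
      next
    }
    Xo <- orthogonalizeBlock(blocks[[k]], Tacc)
    scoreMap <- if (ncol(Tacc)) {
      solve(crossprod(Tacc), crossprod(Tacc, blocks[[k]]))
    }
    # extract at most lvs[k] components; a block whose information is
    # already spanned by earlier scores contributes fewer (possibly zero)
    sub <- .nipalsPls1(Xo, resid, lvs[k], strict = FALSE)
    if (is.null(sub)) {
      entries[[k]] <- list(spec = spec, nLv = 0L, pls = NULL,
                           scoreMap = NULL, mcMeans = mcm)
      next
    }
    fittedK <- predict(sub, Xo)
    resid <- resid - fittedK
    Tacc <- cbind(Tacc, sub@scores)
    entries[[k]] <- list(spec = spec, nLv = sub@nLv, pls = sub,
                         scoreMap = scoreMap, mcMeans = mcm)
  }
  new("SportModel", entries = entries, yMean = yMean,
      fitted = y - resid, residuals = resid,
      wavenumbers = as.numeric(wavenumbers))
}

setMethod("show", "SportModel", function(object) {
  act <- vapply(object@entries, function(e) e$nLv, 0L)
  lab <- vapply(object@entries, function(e) {
    if (!is.null(e$spec)) e$spec@label else "block"
  }, "")
  cat("SportModel:", paste(sprintf("%s(%d LV)", lab, act), collapse = " -> "),
      "\n")
})

# Preprocess a raw spectra matrix with an entry's stored recipe, using the
# training-set centering means.
.applyStoredPreproc <- function(entry, Xraw) {
  spec <- entry$spec
  if (is.null(spec)) {
    stop("model was fitted from bare matrices; supply preprocessed blocks")
  }
  m <- Xraw
  for (step in spec@steps) {
    m <- switch(step,
      snv = snv(m),
      d1 = savgolDerivative(m, 1L, spec@sgWindow, spec@sgPolyorder),
      d2 = savgolDerivative(m, 2L, spec@sgWindow, spec@sgPolyorder),
      mc = meanCenter(m, entry$mcMeans)
    )
  }
  m
}

#' Predict from a SPORT model
#'
#' New samples follow the training chain exactly: each entry's block is
#' preprocessed with the stored recipe (training centering means),
#' orthogonalized against the earlier entries' score contributions through
#' the stored score-to-block regression map, and pushed through the entry's
#' PLS score path; the prediction is the response mean plus the sub-model
#' contributions.
#'
#' @param object a fitted [SportModel-class].
#' @param newdata either a list of preprocessed matrices (one per entry, as
#'   used in [fitSport()]) or raw spectra (matrix, [SpectraBlock-class] or
#'   [NirDataset-class]) when the model stores preprocessing recipes.
#' @return numeric predictions, mg/kg.
#' @export
setMethod("predict", "SportModel", function(object, newdata) {
  entries <- object@entries
  rawInput <- !is.list(newdata)
  if (rawInput) {
    Xraw <- .asMatrix(newdata)
    if (is(newdata, "SpectraBlock") || is(newdata, "NirDataset")) {
      wn <- if (is(newdata, "NirDataset")) newdata@block@wavenumbers else newdata@wavenumbers
      if (length(object@wavenumbers) &&
          (length(wn) != length(object@wavenumbers) ||
           max(abs(wn - object@wavenumbers)) > 1e-6)) {
        stop("wavenumber axis mismatch between model and new spectra")
      }
    }
    nNew <- nrow(Xraw)
  } else {
    if (length(newdata) != length(entries)) {
      stop("newdata must supply one block per model entry")
    }
    nNew <- nrow(as.matrix(newdata[[1L]]))
  }
  pred <- numeric(nNew)
  TaccNew <- matrix(0, nNew, 0L)
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (e$nLv == 0L) next
    Xk <- if (rawInput) .applyStoredPreproc(e, Xraw) else as.matrix(newdata[[k]])
    if (ncol(Xk) != length(e$pls@xMeans)) {
      stop("block ", k, " has the wrong number of variables")
    }
    if (!is.null(e$scoreMap)) {
      Xk <- Xk - TaccNew[, seq_len(nrow(e$scoreMap)), drop = FALSE] %*% e$scoreMap
    }
    Tn <- .plsNewScores(e$pls, Xk)
    pred <- pred + as.numeric(Tn %*% e$pls@yLoadings) + e$pls@yMean
    TaccNew <- cbind(TaccNew, Tn)
  }
  pred + object@yMean
})

#' @rdname vip
#' @details For a [SportModel-class] the index is computed over the union
#'   of all entries' latent variables: each latent variable is weighted by
#'   the response-residual variance it explains, and every entry's weight
#'   vectors live on the shared wavenumber axis, so
#'   `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with the sum
#'   running over all entries' components. For a single-entry model this
#'   reduces exactly to the plain PLS definition.
#' @export
setMethod("vip", "SportModel", function(object, threshold = 1) {
  active <- Filter(function(e) e$nLv > 0L, object@entries)
  W <- do.call(cbind, lapply(active, function(e) e$pls@weights))
  ssy <- unlist(lapply(active, function(e) {
    e$pls@yLoadings^2 * colSums(e$pls@scores^2)
  }))
  if (sum(ssy) <= 0) stop("model explains zero response variance")
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  p <- nrow(wn)
  sc <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  list(scores = sc, threshold = threshold, flagged = sc > threshold)
})

#' All modeling orders of a set of candidate blocks
#'
#' Sequential multi-block models depend on the block order; the model
#' search therefore enumerates every permutation of the candidate
#' preprocessed blocks.
#'
#' @param blockSpecs list (1 to 4 elements, typically of
#'   [PreprocSpec-class]) or a character vector of block names.
#' @return list of orderings, each an integer vector of block indices with
#'   a `names` attribute when the input is named.
#' @examples
#' length(enumerateOrders(sportBlockSpecs()))
#' @export
enumerateOrders <- function(blockSpecs) {
  k <- length(blockSpecs)
  if (k < 1L || k > 4L) stop("1 to 4 blocks are supported")
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  orders <- perm(seq_len(k))
  nm <- names(blockSpecs)
  if (!is.null(nm)) orders <- lapply(orders, function(o) stats::setNames(o, nm[o]))
  orders
}

#' Serialize a fitted SPORT model to JSON
#'
#' @param model a [SportModel-class].
#' @param path output file path.
#' @return `path`, invisibly. `readSportModel()` restores the model.
#' @export
writeSportModel <- function(model, path) {
  stopifnot(is(model, "SportModel"))
  ser <- lapply(model@entries, function(e) {
    list(
      steps = if (!is.null(e$spec)) e$spec@steps,
      sgWindow = if (!is.null(e$spec)) e$spec@sgWindow,
      sgPolyorder = if (!is.null(e$spec)) e$spec@sgPolyorder,
      label = if (!is.null(e$spec)) e$spec@label,
      nLv = e$nLv,
      pls = if (e$nLv > 0L) list(
        nLv = e$pls@nLv, weights = e$pls@weights, loadings = e$pls@loadings,
        yLoadings = e$pls@yLoadings, scores = e$pls@scores,
        coefficients = e$pls@coefficients, xMeans = e$pls@xMeans,
        yMean = e$pls@yMean
      ),
      scoreMap = e$scoreMap,
      mcMeans = e$mcMeans
    )
  })
  obj <- list(type = "SportModel", yMean = model@yMean,
              fitted = model@fitted, residuals = model@residuals,
              wavenumbers = model@wavenumbers, entries = ser)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSportModel
#' @export
readSportModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(obj$entries$nLv)
  entries <- lapply(seq_len(n), function(k) {
    nLv <- as.integer(obj$entries$nLv[[k]])
    spec <- if (!is.null(obj$entries$steps[[k]])) {
      preprocSpec(unlist(obj$entries$steps[[k]]),
                  as.integer(obj$entries$sgWindow[[k]]),
                  as.integer(obj$entries$sgPolyorder[[k]]),
                  obj$entries$label[[k]])
    }
    pls <- if (nLv > 0L) {
      pe <- lapply(obj$entries$pls, function(x) x[[k]])
      new("PlsModel", nLv = as.integer(pe$nLv),
          weights = as.matrix(pe$weights), loadings = as.matrix(pe$loadings),
          yLoadings = as.numeric(pe$yLoadings), scores = as.matrix(pe$scores),
          coefficients = as.numeric(pe$coefficients),
          xMeans = as.numeric(pe$xMeans), yMean = as.numeric(pe$yMean))
    }
    sm <- obj$entries$scoreMap[[k]]
    mcm <- obj$entries$mcMeans[[k]]
    if (!length(sm)) sm <- NULL # jsonlite reads a JSON null as empty
    if (!length(mcm)) mcm <- NULL
    list(spec = spec, nLv = nLv, pls = pls,
         scoreMap = if (!is.null(sm)) {
           m <- as.matrix(sm)
           storage.mode(m) <- "double"
           m
         },
         mcMeans = if (!is.null(mcm)) as.numeric(mcm))
  })
  new("SportModel", entries = entries, yMean = as.numeric(obj$yMean),
      fitted = as.numeric(obj$fitted), residuals = as.numeric(obj$residuals),
      wavenumbers = as.numeric(obj$wavenumbers))
}
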