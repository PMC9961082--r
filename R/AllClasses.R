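#' @import methods
NULL

#' SpectraBlock: an aligned set of absorbance spectra
#'
#' Container for a set of absorbance spectra sharing one wavenumber axis.
#' Rows are individual spectra (one physical measurement each); replicate
#' measurements of the same mixture carry the same `sampleIds` entry and
#' distinct `replicateIds`. The axis is stored strictly ascending; readers
#' and constructors reorder descending input.
#'
#' @slot wavenumbers numeric, strictly increasing axis in cm^-1.
#' @slot absorbance numeric matrix, spectra in rows, one column per
#'   wavenumber.
#' @slot sampleIds character, one id per row.
#' @slot replicateIds integer, replicate index per row (>= 1).
#' @aliases SpectraBlock-class
#' @exportClass SpectraBlock
setClass("SpectraBlock",
  representation(
    wavenumbers = "numeric",
    absorbance = "matrix",
    sampleIds = "character",
    replicateIds = "integer"
  )
)

setValidity("SpectraBlock", function(object) {
  wn <- object@wavenumbers
  ab <- object@absorbance
  msg <- character()
  if (length(wn) < 2L) {
    msg <- c(msg, "need at least two wavenumbers")
  } else if (any(diff(wn) <= 0)) {
    msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  if (!is.numeric(ab)) msg <- c(msg, "absorbance must be numeric")
  if (ncol(ab) != length(wn)) {
    msg <- c(msg, sprintf(
      "absorbance has %d columns but axis has %d points", ncol(ab), length(wn)
    ))
  }
  if (any(!is.finite(ab))) msg <- c(msg, "absorbance contains non-finite values")
  if (length(object@sampleIds) != nrow(ab)) {
    msg <- c(msg, "sampleIds length must equal the number of spectra")
  }
  if (length(object@replicateIds) != nrow(ab)) {
    msg <- c(msg, "replicateIds length must equal the number of spectra")
  }
  if (length(object@replicateIds) && any(object@replicateIds < 1L)) {
    msg <- c(msg, "replicateIds must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' NirDataset: spectra joined with the response and mixture metadata
#'
#' A [SpectraBlock-class] aligned with the regression response (API
#' concentration in mg/kg, one value per spectrum; replicates of a sample
#' share the value) and with one mixture-composition record per spectrum.
#'
#' @slot block a `SpectraBlock`.
#' @slot response numeric, mg/kg, one value per spectrum row.
#' @slot metadata data.frame with one row per spectrum (mixture masses,
#'   stock concentrations, derived concentration); may have zero columns
#'   for purely synthetic responses.
#' @aliases NirDataset-class
#' @exportClass NirDataset
setClass("NirDataset",
  representation(
    block = "SpectraBlock",
    response = "numeric",
    metadata = "data.frame"
  )
)

setValidity("NirDataset", function(object) {
  n <- nrow(object@block@absorbance)
  msg <- character()
  if (length(object@response) != n) {
    msg <- c(msg, "response length must equal the number of spectra")
  }
  if (any(!is.finite(object@response))) {
    msg <- c(msg, "response contains non-finite values")
  }
  if (nrow(object@metadata) && nrow(object@metadata) != n) {
    msg <- c(msg, "metadata must have one row per spectrum")
  }
  sid <- object@block@sampleIds
  if (length(sid) && length(object@response) == n) {
    same <- tapply(object@response, sid, function(v) diff(range(v)) < 1e-6)
    if (any(!same)) {
      msg <- c(msg, "replicate spectra of one sample must share one response")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PreprocSpec: an ordered spectral pretreatment recipe
#'
#' Ordered composition of the supported pretreatments: `"snv"` (standard
#' normal variate), `"d1"`/`"d2"` (Savitzky-Golay first/second derivative)
#' and `"mc"` (mean centering, learned on the training set). When present,
#' `"mc"` must come last; each derivative may appear at most once.
#'
#' @slot steps character vector, subset of `c("snv", "d1", "d2", "mc")`.
#' @slot sgWindow odd integer, Savitzky-Golay window length in points.
#' @slot sgPolyorder integer, Savitzky-Golay polynomial degree.
#' @slot label character, display label.
#' @aliases PreprocSpec-class
#' @exportClass PreprocSpec
setClass("PreprocSpec",
  representation(
    steps = "character",
    sgWindow = "integer",
    sgPolyorder = "integer",
    label = "character"
  )
)

setValidity("PreprocSpec", function(object) {
  msg <- character()
  steps <- object@steps
  bad <- setdiff(steps, c("snv", "d1", "d2", "mc"))
  if (length(bad)) msg <- c(msg, paste("unknown steps:", paste(bad, collapse = ", ")))
  if ("mc" %in% steps && match("mc", steps) != length(steps)) {
    msg <- c(msg, "'mc' must be the last step")
  }
  if (sum(steps == "d1") > 1L || sum(steps == "d2") > 1L) {
    msg <- c(msg, "each derivative may appear at most once")
  }
  if (object@sgWindow %% 2L != 1L) msg <- c(msg, "sgWindow must be odd")
  if (object@sgWindow <= object@sgPolyorder) {
    msg <- c(msg, "sgWindow must exceed sgPolyorder")
  }
  if (length(msg)) msg else TRUE
})

#' PlsModel: a fitted single-response PLS regression
#'
#' NIPALS PLS1 fit with X-deflation. Prediction through the regression
#' vector `coefficients` and through the weights/loadings score path agree
#' to numerical precision; score columns are mutually orthogonal.
#'
#' @slot nLv integer, number of extracted latent variables.
#' @slot weights p x A weight matrix W (unit-norm columns).
#' @slot loadings p x A X-loading matrix P.
#' @slot yLoadings numeric length A, response loadings q.
#' @slot scores n x A training score matrix T.
#' @slot coefficients numeric length p, regression vector for centered data.
#' @slot xMeans numeric length p, training column means.
#' @slot yMean numeric, training response mean.
#' @aliases PlsModel-class
#' @exportClass PlsModel
setClass("PlsModel",
  representation(
    nLv = "integer",
    weights = "matrix",
    loadings = "matrix",
    yLoadings = "numeric",
    scores = "matrix",
    coefficients = "numeric",
    xMeans = "numeric",
    yMean = "numeric"
  )
)

setValidity("PlsModel", function(object) {
  msg <- character()
  a <- object@nLv
  if (ncol(object@weights) != a || ncol(object@loadings) != a ||
      length(object@yLoadings) != a || ncol(object@scores) != a) {
    msg <- c(msg, "latent-variable dimensions are inconsistent")
  }
  if (length(object@coefficients) != nrow(object@weights) ||
      length(object@xMeans) != nrow(object@weights)) {
    msg <- c(msg, "variable dimensions are inconsistent")
  }
  if (a >= 2L) {
    tt <- crossprod(object@scores)
    off <- max(abs(tt[upper.tri(tt)]))
    if (off > 1e-8 * max(diag(tt))) {
      msg <- c(msg, "score columns are not mutually orthogonal")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SportModel: a sequential orthogonalized multi-block PLS chain
#'
#' Ordered chain of PLS sub-models over differently preprocessed copies of
#' one spectral block. Each entry's block is orthogonalized against the
#' scores accumulated from all earlier entries and fitted to the current
#' response residuals; entries assigned 0 latent variables are skipped.
#'
#' Each element of `entries` is a list with components `spec`
#' ([PreprocSpec-class] or `NULL` when fitted from bare matrices), `nLv`,
#' `pls` (the sub [PlsModel-class], `NULL` when `nLv == 0`), `scoreMap`
#' (regression of the entry's training block onto the accumulated scores,
#' used to orthogonalize new samples) and `mcMeans` (training column means
#' of the preprocessed block when the entry's spec ends in `"mc"`).
#'
#' @slot entries list of per-block entries (see Details).
#' @slot yMean numeric, calibration response mean (absorbed once).
#' @slot fitted numeric, training fitted values.
#' @slot residuals numeric, final response residuals.
#' @slot wavenumbers numeric, shared axis (may be length 0 when fitted from
#'   bare matrices).
#' @aliases SportModel-class
#' @exportClass SportModel
setClass("SportModel",
  representation(
    entries = "list",
    yMean = "numeric",
    fitted = "numeric",
    residuals = "numeric",
    wavenumbers = "numeric"
  )
)

setValidity("SportModel", function(object) {
  msg <- character()
  if (!length(object@entries)) msg <- c(msg, "need at least one entry")
  active <- Filter(function(e) e$nLv > 0L, object@entries)
  if (!length(active)) msg <- c(msg, "at least one entry must have nLv > 0")
  if (length(active) >= 2L) {
    tall <- do.call(cbind, lapply(active, function(e) e$pls@scores))
    tt <- crossprod(tall)
    off <- max(abs(tt[upper.tri(tt)]))
    if (off > 1e-8 * max(diag(tt))) {
      msg <- c(msg, "cross-entry score orthogonality violated")
    }
  }
  if (length(msg)) msg else TRUE
})
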