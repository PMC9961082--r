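#' Construct a SpectraBlock
#'
#' Builds the package's spectra container from a wavenumber axis and a
#' samples x wavenumbers absorbance matrix. A descending axis is accepted
#' and normalized to ascending order with the columns permuted accordingly.
#'
#' @param wavenumbers numeric axis in cm^-1, strictly monotone.
#' @param absorbance numeric matrix, one spectrum per row.
#' @param sampleIds sample identifier per row (coerced to character);
#'   defaults to the row number.
#' @param replicateIds integer replicate index per row; defaults to the
#'   occurrence count within each sample id.
#' @param x object to access.
#' @return a [SpectraBlock-class].
#' @examples
#' blk <- spectraBlock(seq(4000, 4040, 4), matrix(rnorm(22), 2))
#' nSpectra(blk)
#' @export
spectraBlock <- function(wavenumbers, absorbance, sampleIds = NULL,
                         replicateIds = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) >= 2 && all(diff(wavenumbers) < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  n <- nrow(absorbance)
  if (is.null(sampleIds)) sampleIds <- as.character(seq_len(n))
  sampleIds <- as.character(sampleIds)
  if (is.null(replicateIds)) {
    replicateIds <- stats::ave(seq_len(n), sampleIds, FUN = seq_along)
  }
  replicateIds <- as.integer(replicateIds)
  dimnames(absorbance) <- NULL
  new("SpectraBlock", wavenumbers = wavenumbers, absorbance = absorbance,
      sampleIds = sampleIds, replicateIds = replicateIds)
}

#' @rdname spectraBlock
#' @export
setMethod("wavenumbers", "SpectraBlock", function(x) x@wavenumbers)

#' @rdname spectraBlock
#' @export
setMethod("absorbance", "SpectraBlock", function(x) x@absorbance)

#' @rdname spectraBlock
#' @export
setMethod("sampleIds", "SpectraBlock", function(x) x@sampleIds)

#' @rdname spectraBlock
#' @export
setMethod("replicateIds", "SpectraBlock", function(x) x@replicateIds)

#' @rdname spectraBlock
#' @export
nSpectra <- function(x) {
  if (is(x, "NirDataset")) x <- x@block
  nrow(x@absorbance)
}

setMethod("show", "SpectraBlock", function(object) {
  wn <- object@wavenumbers
  cat(sprintf(
    "SpectraBlock: %d spectra x %d wavenumbers (%g-%g cm^-1, %d samples)\n",
    nrow(object@absorbance), length(wn), min(wn), max(wn),
    length(unique(object@sampleIds))
  ))
})

#' Construct a NirDataset
#'
#' Joins a [SpectraBlock-class] with its regression response (API
#' concentration, mg/kg, one value per spectrum) and optional per-spectrum
#' mixture metadata.
#'
#' @param block a `SpectraBlock`.
#' @param response numeric, mg/kg, one value per spectrum row.
#' @param metadata data.frame with one row per spectrum (optional).
#' @param x object to access.
#' @return a [NirDataset-class].
#' @export
nirDataset <- function(block, response, metadata = NULL) {
  if (is.null(metadata)) metadata <- data.frame()[seq_along(response), , drop = FALSE]
  rownames(metadata) <- NULL
  new("NirDataset", block = block, response = as.numeric(response),
      metadata = metadata)
}

#' @rdname nirDataset
#' @export
setMethod("responses", "NirDataset", function(x) x@response)

#' @rdname nirDataset
#' @export
setMethod("mixtureMetadata", "NirDataset", function(x) x@metadata)

#' @rdname nirDataset
#' @export
setMethod("wavenumbers", "NirDataset", function(x) x@block@wavenumbers)

#' @rdname nirDataset
#' @export
setMethod("absorbance", "NirDataset", function(x) x@block@absorbance)

#' @rdname nirDataset
#' @export
setMethod("sampleIds", "NirDataset", function(x) x@block@sampleIds)

#' @rdname nirDataset
#' @export
setMethod("replicateIds", "NirDataset", function(x) x@block@replicateIds)

setMethod("show", "NirDataset", function(object) {
  cat(sprintf(
    "NirDataset: %d spectra, %d samples, response %g-%g mg/kg\n",
    nSpectra(object), length(unique(sampleIds(object))),
    min(object@response), max(object@response)
  ))
})

#' Subset a NirDataset by spectrum rows
#'
#' @param x a [NirDataset-class].
#' @param i integer or logical row index.
#' @param j,drop,... ignored.
#' @return the row subset, a `NirDataset`.
#' @export
setMethod("[", "NirDataset", function(x, i, j, ..., drop = FALSE) {
  blk <- x@block
  nb <- new("SpectraBlock",
    wavenumbers = blk@wavenumbers,
    absorbance = blk@absorbance[i, , drop = FALSE],
    sampleIds = blk@sampleIds[i],
    replicateIds = blk@replicateIds[i]
  )
  md <- x@metadata[i, , drop = FALSE]
  rownames(md) <- NULL
  new("NirDataset", block = nb, response = x@response[i], metadata = md)
})
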