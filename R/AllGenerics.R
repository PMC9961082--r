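#' @rdname spectraBlock
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname spectraBlock
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname spectraBlock
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname spectraBlock
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' @rdname nirDataset
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname nirDataset
#' @export
setGeneric("mixtureMetadata", function(x) standardGeneric("mixtureMetadata"))

#' Variable importance in projection
#'
#' Per-variable influence index of a fitted latent-variable regression.
#' Squared VIP scores average to exactly 1, so scores above 1 flag
#' variables with above-average contribution to the model.
#'
#' @param object a fitted [PlsModel-class] or [SportModel-class].
#' @param threshold flagging threshold on the VIP score (default 1).
#' @return list with `scores` (one per variable), `threshold`, and
#'   `flagged` (logical, `scores > threshold`).
#' @export
setGeneric("vip", function(object, threshold = 1) standardGeneric("vip"))

#' @rdname fitPls
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
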