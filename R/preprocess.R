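#' Define a preprocessing recipe
#'
#' @param steps character vector, ordered subset of
#'   `c("snv", "d1", "d2", "mc")` (case-insensitive). `"mc"`, when present,
#'   must be last.
#' @param sgWindow Savitzky-Golay window length in points (odd, default 19).
#' @param sgPolyorder Savitzky-Golay polynomial degree (default 3).
#' @param label display label; defaults to the steps joined by `+`.
#' @return a [PreprocSpec-class].
#' @examples
#' preprocSpec(c("snv", "d2", "mc"))
#' @export
preprocSpec <- function(steps, sgWindow = 19L, sgPolyorder = 3L,
                        label = NULL) {
  steps <- tolower(as.character(steps))
  if (is.null(label)) label <- paste(toupper(steps), collapse = "+")
  new("PreprocSpec", steps = steps, sgWindow = as.integer(sgWindow),
      sgPolyorder = as.integer(sgPolyorder), label = label)
}

setMethod("show", "PreprocSpec", function(object) {
  cat(sprintf("PreprocSpec: %s (SG window %d, degree %d)\n",
              object@label, object@sgWindow, object@sgPolyorder))
})

#' The six single-block model recipes
#'
#' The candidate pretreatments compared under the single-block strategy:
#' raw (mean centering only), SNV, first derivative, second derivative, and
#' SNV followed by each derivative — all with mean centering last.
#'
#' @return named list of [PreprocSpec-class] objects.
#' @export
strategy1Specs <- function() {
  list(
    raw = preprocSpec("mc", label = "Raw (+MC)"),
    snv = preprocSpec(c("snv", "mc"), label = "SNV (+MC)"),
    d1 = preprocSpec(c("d1", "mc"), label = "D1 (+MC)"),
    d2 = preprocSpec(c("d2", "mc"), label = "D2 (+MC)"),
    snv_d1 = preprocSpec(c("snv", "d1", "mc"), label = "SNV+D1 (+MC)"),
    snv_d2 = preprocSpec(c("snv", "d2", "mc"), label = "SNV+D2 (+MC)")
  )
}

#' The four candidate blocks for the multi-block strategy
#'
#' Mean centering only, SNV, first derivative and second derivative — the
#' differently preprocessed copies of one spectral block that the
#' sequential multi-block model fuses. Subsets are reachable in the model
#' search by assigning a block 0 latent variables.
#'
#' @return named list of [PreprocSpec-class] objects.
#' @export
sportBlockSpecs <- function() {
  list(
    mc = preprocSpec("mc", label = "MC"),
    snv = preprocSpec(c("snv", "mc"), label = "SNV"),
    d1 = preprocSpec(c("d1", "mc"), label = "D1"),
    d2 = preprocSpec(c("d2", "mc"), label = "D2")
  )
}

.asMatrix <- function(x) {
  if (is(x, "NirDataset")) return(x@block@absorbance)
  if (is(x, "SpectraBlock")) return(x@absorbance)
  as.matrix(x)
}

#' Standard normal variate
#'
#' Standardizes each spectrum (row) to mean 0 and standard deviation 1
#' (sample sd, `n - 1` denominator), removing per-spectrum multiplicative
#' gain and additive offset.
#'
#' @param x spectra matrix (rows = spectra), [SpectraBlock-class] or
#'   [NirDataset-class]; matrices are returned as matrices.
#' @return the transformed spectra, same shape as the input matrix.
#' @examples
#' snv(matrix(1:3, nrow = 1))
#' @export
snv <- function(x) {
  m <- .asMatrix(x)
  if (ncol(m) < 2L) stop("spectra need at least 2 points for SNV")
  rm <- rowMeans(m)
  centered <- m - rm
  rsd <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  bad <- which(rsd == 0)
  if (length(bad)) {
    stop("zero-variance spectrum in row(s): ", paste(bad, collapse = ", "))
  }
  centered / rsd
}

#' Savitzky-Golay derivative
#'
#' Per-spectrum local least-squares polynomial derivative. Output has the
#' same length as the input: edge points come from the boundary polynomial
#' fits rather than being truncated, so all preprocessed blocks stay on one
#' shared wavenumber axis. Derivatives are per point (no division by the
#' grid spacing); single-block PLS predictions are invariant to that
#' constant factor.
#'
#' @param x spectra matrix (rows = spectra), [SpectraBlock-class] or
#'   [NirDataset-class].
#' @param order derivative order, 1 or 2.
#' @param window window length in points (odd), default 19.
#' @param polyorder fitted polynomial degree (>= `order`), default 3.
#' @return matrix of derivative spectra.
#' @export
savgolDerivative <- function(x, order, window = 19L, polyorder = 3L) {
  m <- .asMatrix(x)
  order <- as.integer(order)
  if (!order %in% 1:2) stop("order must be 1 or 2")
  if (window %% 2L != 1L) stop("window must be odd")
  if (polyorder < order) stop("polyorder must be >= derivative order")
  if (ncol(m) < window) {
    stop(sprintf("spectra have %d points, shorter than the %d-point window",
                 ncol(m), window))
  }
  filt <- signal::sgolay(p = polyorder, n = window, m = order)
  out <- t(apply(m, 1L, function(r) signal::sgolayfilt(r, filt)))
  dimnames(out) <- NULL
  out
}

#' Mean centering with stored training means
#'
#' Training call (`columnMeans = NULL`) computes the column means, subtracts
#' them, and stores them in the `"columnMeans"` attribute of the result.
#' Application call subtracts the supplied means — used to project test
#' spectra with calibration statistics only.
#'
#' @param x spectra matrix (rows = spectra), [SpectraBlock-class] or
#'   [NirDataset-class].
#' @param columnMeans numeric vector of stored training means, or `NULL` to
#'   learn them from `x`.
#' @return centered matrix with attribute `"columnMeans"`.
#' @export
meanCenter <- function(x, columnMeans = NULL) {
  m <- .asMatrix(x)
  if (is.null(columnMeans)) columnMeans <- colMeans(m)
  if (length(columnMeans) != ncol(m)) {
    stop(sprintf("stored means have length %d but spectra have %d points",
                 length(columnMeans), ncol(m)))
  }
  out <- m - rep(columnMeans, each = nrow(m))
  attr(out, "columnMeans") <- columnMeans
  out
}

#' Apply a preprocessing recipe to training and test spectra
#'
#' Row-wise operators (SNV and the Savitzky-Golay derivatives) act on every
#' spectrum independently on both sets; mean centering is learned on the
#' training block only and applied to both, so no test statistic leaks into
#' the calibration.
#'
#' @param spec a [PreprocSpec-class].
#' @param train training spectra (matrix, [SpectraBlock-class] or
#'   [NirDataset-class]).
#' @param test optional test spectra on the same axis.
#' @return list with `train`, `test` (or `NULL`) and `mcMeans` (the stored
#'   training column means, or `NULL` when the recipe has no `"mc"` step).
#' @examples
#' pp <- applyPreproc(preprocSpec(c("snv", "mc")), matrix(rnorm(40), 4))
#' colMeans(pp$train)
#' @export
applyPreproc <- function(spec, train, test = NULL) {
  stopifnot(is(spec, "PreprocSpec"))
  validObject(spec)
  tr <- .asMatrix(train)
  te <- if (!is.null(test)) .asMatrix(test)
  mcMeans <- NULL
  for (step in spec@steps) {
    if (step == "snv") {
      tr <- snv(tr)
      if (!is.null(te)) te <- snv(te)
    } else if (step %in% c("d1", "d2")) {
      ord <- if (step == "d1") 1L else 2L
      tr <- savgolDerivative(tr, ord, spec@sgWindow, spec@sgPolyorder)
      if (!is.null(te)) te <- savgolDerivative(te, ord, spec@sgWindow, spec@sgPolyorder)
    } else if (step == "mc") {
      tr <- meanCenter(tr)
      mcMeans <- attr(tr, "columnMeans")
      if (!is.null(te)) te <- meanCenter(te, mcMeans)
    }
  }
  list(train = tr, test = te, mcMeans = mcMeans)
}
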