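#' Default NIR band library for the three mixture components
#'
#' Pure-component absorbance models as sums of Gaussian bands on the
#' 4000-10,000 cm^-1 axis. Band placement follows the overtone/combination
#' regions that dominate NIR spectra of carbohydrates and corticosteroids:
#' O-H first overtone and combination around 6900-7000 and 5100-5200 cm^-1
#' for both excipients, C-H combination bands around 4300-4400 and 5800
#' cm^-1, and, for the API, additional C-H second overtone/combination
#' structure near 8550, 7950 and 7350 cm^-1 plus carbonyl-associated
#' combination bands near 5290, 4700 and 4600 cm^-1. API bands are
#' narrower than the broad carbohydrate O-H/C-H envelopes, and their
#' per-unit-mass intensities are set well above the excipients' so that,
#' at dosage fractions of a few thousand mg/kg under the default artifact
#' model, cross-validated calibration accuracy lands in the range reported
#' for laboratory NIR quantification of this system.
#'
#' @return named list with one matrix per component (`api`, `starch`,
#'   `lactose`); columns `center` (cm^-1), `width` (Gaussian sigma, cm^-1),
#'   `amplitude` (absorbance units).
#' @export
defaultBandLibrary <- function() {
  mk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "width", "amplitude")
    m
  }
  list(
    api = mk(
      8550, 40, 5.3,
      7950, 38, 3.8,
      7350, 40, 4.3,
      5950, 35, 2.9,
      5290, 32, 6.7,
      4700, 28, 3.6,
      4600, 26, 4.3,
      4360, 26, 2.4
    ),
    starch = mk(
      8330, 300, 0.18,
      6900, 260, 0.90,
      5780, 200, 0.35,
      5180, 200, 1.00,
      4750, 160, 0.45,
      4390, 120, 0.55
    ),
    lactose = mk(
      8380, 280, 0.15,
      6820, 200, 0.80,
      6290, 120, 0.35,
      5920, 170, 0.30,
      5160, 160, 1.10,
      4700, 130, 0.60,
      4280, 110, 0.60
    )
  )
}

#' Simulator configuration
#'
#' Parameters of the synthetic FT-NIR acquisition model. Defaults emulate
#' the study conditions exercised throughout the package: a 4000-10,000
#' cm^-1 axis at 4 cm^-1 spacing (1501 points), two replicate spectra per
#' mixture with independent artifact draws, constant multiplicative
#' scatter (sd 0.05) plus a smooth wavelength-dependent scatter field (sd
#' 0.25, 8 component pairs), additive baseline offset (sd 0.02) and tilt
#' (sd 0.01), and white noise (sd 0.003 absorbance units).
#'
#' @param wavenumberStart,wavenumberEnd,wavenumberStep axis in cm^-1.
#' @param bandLibrary per-component band list, see [defaultBandLibrary()].
#' @param scatterSd sd of the constant part of the multiplicative scatter
#'   gain around 1 (unitless).
#' @param scatterSmoothSd overall sd of the smooth wavelength-dependent
#'   part of the multiplicative scatter field (unitless): low-frequency
#'   cosine/sine components over the axis with 1/j amplitude decay — the
#'   particle-size scatter of powder measurements, which defeats
#'   raw-spectrum models and motivates SNV/derivative pretreatment.
#' @param scatterComponents number of low-frequency component pairs in the
#'   scatter field (default 4).
#' @param offsetSd sd of the additive baseline offset (absorbance).
#' @param slopeSd sd of the linear baseline slope across the axis
#'   (absorbance over the full range).
#' @param noiseSd sd of iid Gaussian noise per point (absorbance).
#' @param replicates replicate spectra per mixture (>= 1).
#' @param seed integer seed used by [simulateNirDataset()]; `NA` leaves the
#'   RNG state alone.
#' @return a validated configuration list of class `simConfig`.
#' @export
simConfig <- function(wavenumberStart = 4000, wavenumberEnd = 10000,
                      wavenumberStep = 4, bandLibrary = defaultBandLibrary(),
                      scatterSd = 0.05, scatterSmoothSd = 0.25,
                      scatterComponents = 8L, offsetSd = 0.02,
                      slopeSd = 0.01, noiseSd = 0.003, replicates = 2L,
                      seed = NA_integer_) {
  if (wavenumberStep <= 0 || wavenumberEnd <= wavenumberStart) {
    stop("wavenumber grid must be strictly increasing")
  }
  sds <- c(scatterSd, scatterSmoothSd, offsetSd, slopeSd, noiseSd)
  if (any(sds < 0)) stop("sd parameters must be non-negative")
  if (replicates < 1) stop("replicates must be >= 1")
  if (scatterComponents < 0) stop("scatterComponents must be >= 0")
  structure(
    list(
      grid = seq(wavenumberStart, wavenumberEnd, by = wavenumberStep),
      bandLibrary = bandLibrary, scatterSd = scatterSd,
      scatterSmoothSd = scatterSmoothSd,
      scatterComponents = as.integer(scatterComponents),
      offsetSd = offsetSd, slopeSd = slopeSd, noiseSd = noiseSd,
      replicates = as.integer(replicates), seed = seed
    ),
    class = "simConfig"
  )
}

#' Evaluate a pure-component spectrum as a sum of Gaussian bands
#'
#' @param bands matrix with columns `center`, `width`, `amplitude`; an
#'   empty band list yields the zero spectrum.
#' @param grid wavenumber axis (cm^-1), strictly monotone.
#' @return non-negative absorbance vector on `grid`.
#' @examples
#' g <- seq(4000, 10000, 4)
#' s <- simulatePureSpectrum(cbind(7000, 100, 1), g)
#' g[which.max(s)]
#' @export
simulatePureSpectrum <- function(bands, grid) {
  if (is.unsorted(grid, strictly = TRUE) && is.unsorted(rev(grid), strictly = TRUE)) {
    stop("grid must be strictly monotone")
  }
  out <- numeric(length(grid))
  if (is.null(bands) || NROW(bands) == 0L) return(out)
  bands <- matrix(as.numeric(bands), ncol = 3)
  if (any(bands[, 2L] <= 0)) stop("band widths must be positive")
  for (i in seq_len(nrow(bands))) {
    out <- out + bands[i, 3L] * exp(-0.5 * ((grid - bands[i, 1L]) / bands[i, 2L])^2)
  }
  out
}

#' Simulate an NIR mixture dataset
#'
#' For each design row and replicate, draws one spectrum
#' \deqn{x = m(u) (f_{api} s_{api} + f_{st} s_{st} + f_{lac} s_{lac})
#'   + b_0 + b_1 u + \epsilon,}
#' where the `f` are the component mass fractions of the mixture, the `s`
#' are the pure-component band spectra,
#' `m(u)` is a smooth multiplicative scatter field over the normalized
#' axis position `u` in `[0, 1]`:
#' `m(u) = 1 + g0 + sum_j (a_j cos(j pi u) + c_j sin(j pi u)) / j`, with
#' `g0 ~ N(0, scatterSd)` and `a_j, c_j ~ N(0, scatterSmoothSd)` drawn per
#' spectrum (the particle-size scatter of powder measurements),
#' `b0 ~ N(0, offsetSd)` and `b1 ~ N(0, slopeSd)` give an additive tilted
#' baseline, and `eps` is iid `N(0, noiseSd)` per point. Replicates share
#' the composition but draw independent artifacts, emulating repacked
#' aliquots of one mixture. The response is the API concentration in
#' mg/kg (full precision).
#'
#' @param design data.frame as returned by [mixtureDesign()] (masses and
#'   stock concentrations per sample).
#' @param config a [simConfig()].
#' @return a [NirDataset-class] with `replicates x nrow(design)` spectra.
#' @examples
#' ds <- simulateNirDataset(mixtureDesign(), simConfig(seed = 1))
#' nSpectra(ds)
#' @export
simulateNirDataset <- function(design, config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  if (!NROW(design)) stop("design must be non-empty")
  if (!is.na(config$seed)) set.seed(config$seed)
  grid <- config$grid
  u <- (grid - grid[1L]) / (grid[length(grid)] - grid[1L])
  frac <- .massFractions(design)
  if (any(abs(rowSums(frac) - 1) > 1e-8)) {
    stop("component mass fractions must sum to 1")
  }
  pure <- rbind(
    api = simulatePureSpectrum(config$bandLibrary$api, grid),
    starch = simulatePureSpectrum(config$bandLibrary$starch, grid),
    lactose = simulatePureSpectrum(config$bandLibrary$lactose, grid)
  )
  clean <- frac %*% pure # one ideal spectrum per sample
  n <- nrow(design) * config$replicates
  X <- matrix(0, n, length(grid))
  sid <- character(n)
  rid <- integer(n)
  row <- 0L
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(config$replicates)) {
      row <- row + 1L
      gain <- 1 + stats::rnorm(1L, 0, config$scatterSd)
      for (j in seq_len(config$scatterComponents)) {
        ab <- stats::rnorm(2L, 0, config$scatterSmoothSd) / j
        gain <- gain + ab[1L] * cos(j * pi * u) + ab[2L] * sin(j * pi * u)
      }
      offset <- stats::rnorm(1L, 0, config$offsetSd)
      slope <- stats::rnorm(1L, 0, config$slopeSd)
      noise <- if (config$noiseSd > 0) {
        stats::rnorm(length(grid), 0, config$noiseSd)
      } else 0
      X[row, ] <- gain * clean[i, ] + offset + slope * u + noise
      sid[row] <- as.character(design$sample_id[i])
      rid[row] <- r
    }
  }
  conc <- frac[, "api"] * 1e6
  meta <- design[rep(seq_len(nrow(design)), each = config$replicates), ,
                 drop = FALSE]
  nirDataset(
    spectraBlock(grid, X, sampleIds = sid, replicateIds = rid),
    response = rep(conc, each = config$replicates),
    metadata = meta
  )
}
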