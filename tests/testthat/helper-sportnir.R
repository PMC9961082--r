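# Reduced-axis simulator configuration for fast tests: 4000-7000 cm^-1 at
# 20 cm^-1 spacing (151 points). Band structure and artifact model are the
# package defaults unless overridden.
quickConfig <- function(seed, ...) {
  simConfig(wavenumberStart = 4000, wavenumberEnd = 7000,
            wavenumberStep = 20, seed = seed, ...)
}

quickDataset <- function(seed, ...) {
  simulateNirDataset(mixtureDesign(), quickConfig(seed, ...))
}

# artifact-free configuration (exact linear mixing, noise optional)
cleanConfig <- function(seed = 1, noiseSd = 0, ...) {
  quickConfig(seed, scatterSd = 0, scatterSmoothSd = 0, offsetSd = 0,
              slopeSd = 0, noiseSd = noiseSd, ...)
}
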