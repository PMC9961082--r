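---
title: "Methods: sequential orthogonalized multi-block PLS calibration for NIR quantification"
author: "sportnir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential orthogonalized multi-block PLS calibration for NIR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sportnir)
```

# The calibration problem

The package quantifies a minor active ingredient (dexamethasone, 500–6200
mg/kg) in a binary excipient matrix (corn starch and α-lactose
monohydrate) from near-infrared absorbance spectra over 4000–10,000
cm⁻¹. NIR spectra of powders are dominated by broad excipient
overtone/combination bands and by physical artifacts — particle-size
scatter and baseline drift — that dwarf the analyte signal, so the method
of interest is latent-variable regression after spectral pretreatment.

Two strategies are implemented. *Single-block*: one pretreatment recipe is
applied and a NIPALS PLS1 model fitted. *Multi-block (SPORT)*: several
differently pretreated copies of the same spectra are fused sequentially —
each block is orthogonalized against the latent-variable scores already
extracted from earlier blocks and fitted to the current response
residuals. The chain extracts complementary information that any single
pretreatment would discard, at the cost of a combinatorial model-selection
problem (block order × per-block complexity), which the package solves
exhaustively.

# Models and algorithms

## NIPALS PLS1 (`fitPls`)

Centered `X`, `y`; for each component: `w = X'y/‖X'y‖`, `t = Xw`,
`p = X't/t't`, `q = y't/t't`, deflation `X ← X − tp'`. No scaling is
applied. Numerical choices:

- **Sign convention.** Each weight vector's largest-magnitude element is
  forced positive (its score flips with it), making fits bit-reproducible
  across platforms without changing predictions.
- **Rank guard.** Extraction fails (strict mode, user API) or stops
  early (inside multi-block chains) when `‖X'y‖` or `t't` falls below
  `1e-12 · max|X_c|` — the practical rank of the deflated data is
  exhausted. Inside a SPORT chain a later block that is fully contained in
  the span of earlier scores therefore contributes zero components rather
  than aborting the chain; this also keeps the final refit consistent
  with any configuration visited by the cross-validated search.
- Prediction via `b = W(P'W)⁻¹q` agrees with the sequential score-path
  projection to ~1e-12; the class validity enforces mutually orthogonal
  score columns.

## Pretreatments (`preprocSpec`, `applyPreproc`)

- **SNV** standardizes each spectrum to mean 0, sd 1, using the sample
  (n−1) standard deviation — one convention had to be fixed for exact
  tests; either is defensible. Zero-variance spectra are an error naming
  the row.
- **Savitzky–Golay derivatives** use a 19-point window and cubic
  polynomial by default. The derivative is *per point* (no division by the
  grid spacing): PLS predictions are invariant to a constant factor per
  block, so only the convention needed fixing. Full output length is kept,
  with edge points from the boundary polynomial fits, so all blocks share
  one wavenumber axis for VIP overlays.
- **Mean centering** is learned on the calibration set and applied with
  stored means to any test data; row-wise operators (SNV, derivatives) act
  per spectrum and cannot leak information across the split. In composed
  recipes (`SNV + D2 + MC`) SNV precedes the derivative and MC is always
  last.

## SPORT (`fitSport`, `predict`, `vip`)

The response mean is absorbed once; per block: orthogonalize against the
accumulated scores via an orthonormal (QR, rank-detecting) basis, fit PLS1
to the residuals, append scores, update residuals. Design choices the
method description leaves open, fixed here:

- **Projection of new samples.** Training defines orthogonalization
  against realized training scores; for prediction the package stores, per
  entry, the regression of the entry's training block onto the accumulated
  scores (`scoreMap`). A new spectrum's accumulated score estimates
  (computed recursively through the earlier sub-models' weight/loading
  chains) then subtract `t̂·scoreMap` from its preprocessed block. On the
  training rows this reproduces the training orthogonalization exactly, and
  a single-entry model reduces to plain PLS prediction.
- **Candidate blocks.** Mean-centering only, SNV, D1, D2 — the search runs
  over all permutations of all four; subsets are reachable because a block
  may receive 0 latent variables. This reconciles "search all block
  sequences" with winning chains that use fewer blocks.
- **Multi-block VIP.** No canonical definition exists for score-chained
  multi-block models; the package weights every latent variable of every
  entry by the response(-residual) variance it explains and evaluates
  weights on the shared axis:
  `VIP_j = sqrt(p Σ SSY_a (w_ja/‖w_a‖)² / Σ SSY_a)` over the union of
  components. It reduces exactly to standard VIP for one block, and the
  mean of squared scores is 1 by construction (verified to 1e-10 in the
  tests).

## Validation protocol (`rankedSplit`, `selectLv`, `selectSport`)

- **External split:** distinct samples ranked by ascending concentration
  (ties broken by sample id), every 5th rank to the test set with all its
  replicates: 5 of 27 mixtures → 10 of 54 spectra. The alternative reading
  (ranks 1, 6, 11, …) would yield 6 mixtures / 12 spectra and is rejected
  because the protocol's stated cardinalities are 10 test / 44 calibration.
- **Cross-validation:** 7 folds, contiguous blocks over the
  concentration-ranked distinct samples, replicates grouped with their
  sample. Deterministic (no RNG) — fold assignment is unspecified in the
  protocol, and a reproducible rule keeps every quantity exactly
  re-computable. `R²CV` uses the total sum of squares about the full
  calibration mean.
- **Complexity choice:** the stated "compromise between parsimony and
  RMSECV" is concretized as *the smallest complexity whose RMSECV is
  within 2% of the grid minimum* (`slack = 0.02`, configurable); for SPORT
  the complexity is the total LV count, with remaining ties broken by
  lower RMSECV, then earlier ordering.
- **Search cost:** per fold the grid (24 orderings × 11⁴ LV vectors for
  4 blocks, LVs 0–10) is walked as a prefix tree in compiled code — one
  NIPALS fit serves all truncations and suffixes — and each block is first
  compressed onto an orthonormal basis of its training row space (scores
  and predictions are invariant under this right-rotation; verified
  against the uncompressed path to 1e-8, and the cached walk is
  bit-identical to from-scratch recomputation). A full Strategy-II run on
  54 spectra × 1501 wavenumbers takes ~15 s on one CPU.
- **Hygiene:** both pipelines assert calibration/test disjointness; test
  rows are touched only by the final prediction.
- Both `R²_pred` conventions (sum of squares about the test-set mean and
  about the calibration mean) are reported, since the external-validation
  convention is ambiguous in practice.

# The synthetic-data generator

No measured spectra are deposited with the motivating study; the
package's simulator defines the study conditions under which everything
is tested.

**Composition.** `mixtureDesign()` returns the 27-mixture laboratory
design: masses of starch, lactose and two API stock premixes (31,964 and
32,395 mg/kg API), with the API concentration derived from the masses
(`computeConcentration`, full precision internally, integer mg/kg for
reporting). Three published mass entries (samples 2, 10, 11) are
inconsistent with their own published concentrations and excipient splits
(sample 2 grossly: 0.3953 g starch implies 1745 mg/kg and a 29/71 split
against the stated 843 mg/kg and 67/33); the package uses single-digit
corrections (1.9453, 1.8412, 2.0727 g) that reproduce the stated
concentration column to <0.2 mg/kg and the stated splits. The stated
integers are retained as `api_nominal`.

**Spectra.** Beer–Lambert mixing of three pure-component Gaussian-band
spectra on a 4000–10,000 cm⁻¹ axis with 4 cm⁻¹ spacing (1501 points; the
instrument's nominal resolution is read as grid spacing), two replicates
per mixture, with per-spectrum artifacts:

```
x = m(u) · Σ_c f_c s_c + b₀ + b₁ u + ε,   u ∈ [0,1] normalized axis
m(u) = 1 + g₀ + Σ_{j=1..8} (a_j cos(jπu) + c_j sin(jπu))/j
```

`g₀ ~ N(0, 0.05)` (constant scatter gain), `a_j, c_j ~ N(0, 0.25)`
(smooth wavelength-dependent scatter), `b₀ ~ N(0, 0.02)`,
`b₁ ~ N(0, 0.01)` (baseline), `ε ~ N(0, 0.003)` per point (noise, in
absorbance units). Replicates share `f_c` but draw independent artifacts,
emulating repacked aliquots.

Two generator design points deserve justification:

- **Why a wavelength-dependent scatter field.** A constant gain plus
  linear baseline spans only ~3 interference dimensions, which a 10-LV
  raw-spectrum PLS absorbs trivially — under that minimal artifact model
  raw models *beat* derivative models, inverting the ordering every NIR
  practitioner observes on powders. The smooth random field (the
  EMSC/particle-size-scatter picture) makes the interference
  high-dimensional and smooth: derivatives annihilate it while white
  noise limits them, SNV removes only its constant part, and raw models
  degrade — reproducing the canonical ordering raw ≪ SNV ≪ D1/D2.
- **Band library.** Band centers follow the overtone/combination regions
  of carbohydrates and corticosteroids (both excipients: O–H near
  6800–6900 and 5100–5200 cm⁻¹, C–H near 4300–4400 and 5800 cm⁻¹; API:
  C–H second overtone/combination near 8550, 7950, 7350 cm⁻¹ and
  carbonyl-associated combinations near 5290, 4700, 4600 cm⁻¹). API bands
  are narrow (σ 26–40 cm⁻¹) against broad excipient envelopes (σ
  110–300 cm⁻¹), and API per-mass intensities (2.4–6.7 au) sit well above
  the excipients' (0.15–1.1 au): the defensible intensity scale was
  calibrated once so that, at dosage fractions of a few thousand mg/kg
  under the pinned artifact levels, cross-validated accuracy lands where
  laboratory NIR quantification of this system lands (R²CV ≈ 0.8–0.9 for
  derivative models, external RMSEP of a few hundred mg/kg), then frozen.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: no instrument line-shape or detector model, no
Kubelka–Munk diffuse-reflectance nonlinearity, no wavelength-correlated
noise, no water/temperature band shifts, no chemical interactions between
components (strict linear mixing), and Gaussian bands only. Conclusions
about *relative* method behavior (preprocessing ordering, multi-block
fusion benefit, VIP localization) transfer; absolute error levels do not.

# Measured behavior at the study scale

With the default generator and protocol (27 mixtures × 2 replicates,
1501 wavenumbers, 44/10 split, 7-fold CV, LVs 0–10), across ten seeds the
test suite verifies: median external R² of the Strategy-II pipeline ≥ 0.9,
and second-derivative models beat raw models in R²CV on every seed (median
margin > 0.1). Two honest caveats, both visible in the README example:
with only 10 external spectra the RMSEP is noisy, so the cross-validated
ranking and the external ranking can disagree on a single dataset; and the
composed SNV+D1 single-block recipe — which is not one of the four SPORT
candidate blocks — sometimes cross-validates better than any 4-block
chain. The guaranteed property, asserted in the tests, is the reduction
one: the SPORT search can never be worse than the best *candidate* block
alone by more than the 2% parsimony slack.

# Degenerate inputs and edge behavior

- Exactly noise-free mixtures of three components have centered spectral
  rank 2 (closed system); asking for more components raises the rank
  error in `fitPls`, while SPORT chains cap silently (see above).
- Mixtures with zero total mass, zero-variance responses, zero-variance
  spectra under SNV, spectra shorter than the SG window, ragged or
  non-numeric or non-finite cells in spectra files, missing or duplicate
  sample ids in joins — all abort with located errors; nothing is imputed.
- A SPORT configuration with all blocks at 0 LVs is rejected; in the
  search grid such configurations are reported as `Inf` RMSECV.

# Known limitations

- PLS1 only (single response); no PLS2, kernel PLS, or uncertainty
  intervals.
- The SPORT order search is exhaustive and limited to 4 candidate blocks
  (24 orderings × 11⁴ LV grid); composed pretreatments (e.g. SNV+D1) are
  not candidate blocks, matching the four-pretreatment design.
- JCAMP-DX support covers plain AFFN `(X++(Y..Y))` blocks — enough for
  lossless round-trips of the package's own exports, not a general vendor
  reader.
- The simulator's realism limits are listed above; in particular the
  prediction of real commercial tablets (additional unmodeled excipients)
  is out of scope and only approachable as a simulator scenario with an
  extra component in a custom band library.
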