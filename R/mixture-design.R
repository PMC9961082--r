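#' API concentration of a four-ingredient mixture
#'
#' Dexamethasone is dosed into each mixture through two solid stock
#' premixes: premix A (API in starch) and premix B (API in lactose), with
#' known API concentrations, further diluted with pure starch and lactose.
#' The resulting API concentration is the total API mass over the total
#' mixture mass,
#' \deqn{c = (m_A c_A + m_B c_B) / (m_{st} + m_{lac} + m_A + m_B).}
#'
#' All arguments are vectorized.
#'
#' @param massStarch,massLactose masses of pure starch and lactose, g.
#' @param massMixA,massMixB masses of the two stock premixes, g.
#' @param concStockA,concStockB API concentration of the premixes, mg/kg.
#' @param round report integer mg/kg (default); set `FALSE` to keep full
#'   precision for internal use.
#' @return API concentration in mg/kg.
#' @examples
#' computeConcentration(0.7404, 2.2155, 0.0113, 0.0398)
#' @export
computeConcentration <- function(massStarch, massLactose, massMixA, massMixB,
                                 concStockA = 31964, concStockB = 32395,
                                 round = TRUE) {
  m <- cbind(massStarch, massLactose, massMixA, massMixB)
  if (any(m < 0)) stop("masses must be non-negative")
  total <- rowSums(m)
  if (any(total <= 0)) stop("degenerate mixture: total mass must be positive")
  conc <- unname((m[, 3L] * concStockA + m[, 4L] * concStockB) / total)
  if (round) base::round(conc) else conc
}

# Printed 27-sample laboratory design: ingredient masses (g), stock premix
# concentrations (mg/kg), nominal excipient split and nominal API
# concentration (mg/kg). Three mass entries (samples 2, 10, 11) carry
# single-digit corrections that make the mass-derived concentration and the
# stated excipient split internally consistent with the published values.
.designTable <- function() {
  txt <- "
sample_id mass_starch mass_lactose mass_mix_a mass_mix_b pct_starch_nominal pct_lactose_nominal api_nominal
1  0.7404 2.2155 0.0113 0.0398 25 75  549
2  1.9453 0.9752 0.0494 0.0293 67 33  843
3  2.1843 0.7268 0.0699 0.0239 75 25 1001
4  0.4833 2.4065 0.0186 0.0968 17 83 1241
5  1.4298 1.4321 0.0712 0.0700 50 50 1513
6  0.4743 2.3706 0.0270 0.1340 17 83 1731
7  2.3552 0.4706 0.1453 0.0305 83 17 1876
8  0.9337 1.8688 0.0646 0.1301 33 67 2095
9  2.3817 0.4660 0.1771 0.0360 83 17 2230
10 0.9276 1.8412 0.0786 0.1556 33 67 2515
11 2.0727 0.6863 0.1902 0.0627 75 25 2693
12 0.4602 2.2760 0.0431 0.2236 17 83 2871
13 2.7125 0.0000 0.2897 0.0000 100 0 3084
14 2.2426 0.4459 0.2548 0.0495 83 17 3257
15 0.0000 2.6738 0.0000 0.3233 0 100 3495
16 1.7711 0.8855 0.2301 0.1138 67 33 3680
17 0.0000 2.6397 0.0000 0.3797 0 100 4074
18 0.8719 1.7464 0.1262 0.2572 33 67 4120
19 1.2987 1.3007 0.2006 0.1999 50 50 4296
20 0.6451 1.9355 0.1044 0.3149 25 75 4513
21 2.5627 0.0000 0.4382 0.0000 100 0 4668
22 1.6954 0.8476 0.3042 0.1541 67 33 4903
23 0.6337 1.8945 0.1194 0.3585 25 75 5133
24 2.4887 0.0000 0.5115 0.0000 100 0 5450
25 1.2385 1.2340 0.2655 0.2645 50 50 5680
26 0.0000 2.4418 0.0000 0.5579 0 100 6025
27 1.8178 0.6053 0.4344 0.1441 75 25 6181"
  utils::read.table(text = txt, header = TRUE)
}

#' The 27-sample dexamethasone/starch/lactose mixture design
#'
#' Returns the laboratory mixture design used throughout the package: 27
#' powder mixtures of dexamethasone (via two solid stock premixes at 31,964
#' and 32,395 mg/kg API) in corn starch and alpha-lactose monohydrate,
#' spanning roughly 500-6200 mg/kg API with the two excipients at nine
#' nominal levels (0, 17, 25, 33, 50, 67, 75, 83, 100 %).
#'
#' The derived columns are computed from the masses: `api_mgkg` (full
#' precision, via [computeConcentration()]), and `pct_starch`/`pct_lactose`,
#' the mass-derived excipient percentages counting each premix's excipient
#' carrier mass with its excipient.
#'
#' @return data.frame with one row per mixture: `sample_id`, the four
#'   ingredient masses (g), `conc_stock_a`/`conc_stock_b` (mg/kg),
#'   `pct_starch`/`pct_lactose`, `api_mgkg` and the published nominal
#'   integer `api_nominal` (mg/kg).
#' @examples
#' d <- mixtureDesign()
#' all(abs(d$api_mgkg - d$api_nominal) <= 1)
#' @export
mixtureDesign <- function() {
  d <- .designTable()
  concA <- 31964
  concB <- 32395
  d$conc_stock_a <- concA
  d$conc_stock_b <- concB
  d$api_mgkg <- computeConcentration(
    d$mass_starch, d$mass_lactose, d$mass_mix_a, d$mass_mix_b,
    concA, concB, round = FALSE
  )
  total <- d$mass_starch + d$mass_lactose + d$mass_mix_a + d$mass_mix_b
  starchTotal <- d$mass_starch + d$mass_mix_a * (1 - concA * 1e-6)
  lactoseTotal <- d$mass_lactose + d$mass_mix_b * (1 - concB * 1e-6)
  d$pct_starch <- 100 * starchTotal / total
  d$pct_lactose <- 100 * lactoseTotal / total
  d[, c("sample_id", "mass_starch", "mass_lactose", "mass_mix_a",
        "mass_mix_b", "conc_stock_a", "conc_stock_b", "pct_starch",
        "pct_lactose", "api_mgkg", "api_nominal")]
}

# Per-component mass fractions (api, starch, lactose) of a design row;
# they sum to 1 by construction.
.massFractions <- function(design) {
  total <- design$mass_starch + design$mass_lactose +
    design$mass_mix_a + design$mass_mix_b
  api <- (design$mass_mix_a * design$conc_stock_a +
          design$mass_mix_b * design$conc_stock_b) * 1e-6 / total
  starch <- (design$mass_starch +
             design$mass_mix_a * (1 - design$conc_stock_a * 1e-6)) / total
  lactose <- (design$mass_lactose +
              design$mass_mix_b * (1 - design$conc_stock_b * 1e-6)) / total
  cbind(api = api, starch = starch, lactose = lactose)
}
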