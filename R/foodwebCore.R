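#' @include FoodWebParameters.R
NULL

checkCiliate <- function(C) {
  if (!is.numeric(C) || any(!is.finite(C)))
    stop("ciliate biomass 'C' must be finite and numeric")
  if (any(C < 0))
    stop("ciliate biomass 'C' must be non-negative")
  invisible(C)
}

#' Steady-state prokaryote biomass sustained by a given ciliate biomass
#'
#' At steady state the heterotrophic nanoflagellates balance growth on
#' prokaryotes against losses to ciliate grazing,
#' `yieldH * alphaH * B * H = alphaC * H * C`, which pins the prokaryote
#' standing stock to `B = alphaC * C / (yieldH * alphaH)` -- linear in
#' ciliate biomass and independent of the prokaryote growth rate.
#'
#' @param C ciliate biomass, nmol-P/L (vectorised, non-negative).
#' @param params a [FoodWebParameters-class] object.
#' @return prokaryote biomass in nmol-P/L.
#' @examples
#' p <- foodWebParameters(yieldBC = 1, psi = 1)
#' prokaryoteBiomass(9, p)   # 10 nmol-P/L
#' @export
prokaryoteBiomass <- function(C, params) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(C)
  alphaC(params) * C / (yieldH(params) * alphaH(params))
}

#' Steady-state free phosphate concentration
#'
#' Autotrophic flagellate balance (`alphaA * P * A = alphaC * A * C`) fixes
#' free phosphate at `P = (alphaC / alphaA) * C`.
#'
#' @inheritParams prokaryoteBiomass
#' @return free phosphate in nmol-P/L.
#' @export
freePhosphate <- function(C, params) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(C)
  (alphaC(params) / alphaA(params)) * C
}

#' Steady-state phosphate-limited prokaryote growth rate
#'
#' Under mineral nutrient limitation `mu = alphaB * P`; substituting the
#' steady-state phosphate gives `mu = alphaB * (alphaC / alphaA) * C`.
#'
#' @inheritParams prokaryoteBiomass
#' @return specific growth rate in 1/h.
#' @export
prokaryoteGrowthRate <- function(C, params) {
  stopifnot(is(params, "FoodWebParameters"))
  alphaB(params) * freePhosphate(C, params)
}

## Quadratic coefficient k of the MNL carbon-demand law, BCD_P = k * C^2.
bcdQuadraticCoefficient <- function(params) {
  alphaB(params) * alphaC(params)^2 /
    (yieldBC(params) * yieldH(params) * alphaH(params) * alphaA(params))
}

#' Bacterial carbon demand under mineral nutrient limitation
#'
#' Carbon demand is production over yield, `BCD_P = mu * B / yieldBC`;
#' substituting the closed forms for `mu` and `B` gives the quadratic law
#' `BCD_P = k * C^2` with
#' `k = alphaB * alphaC^2 / (yieldBC * yieldH * alphaH * alphaA)`.
#'
#' @inheritParams prokaryoteBiomass
#' @return carbon demand in nmol-C/L/h.
#' @export
bcdMineralLimited <- function(C, params) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(C)
  bcdQuadraticCoefficient(params) * C^2
}

#' Bacterial carbon demand with the labile-DOC supply ceiling
#'
#' Sustainable carbon consumption cannot exceed the labile-DOC supply rate
#' `psi`, so `BCD = min(k * C^2, psi)`: quadratic in ciliate biomass while
#' mineral-nutrient-limited, flat at `psi` once organic-carbon-limited.
#'
#' @inheritParams prokaryoteBiomass
#' @return carbon demand in nmol-C/L/h, bounded above by `psi`.
#' @export
bcd <- function(C, params) {
  pmin(bcdMineralLimited(C, params), docSupply(params))
}

#' Classify the prokaryote growth-limitation regime
#'
#' Returns `"MNL"` (mineral nutrient limited) where `k * C^2 < psi` and
#' `"OCL"` (organic carbon limited) where `k * C^2 >= psi`.  The tie at the
#' crossover is assigned OCL, making the regime right-continuous in `C`.
#'
#' @inheritParams prokaryoteBiomass
#' @return a factor with levels `MNL`, `OCL`.
#' @export
classifyRegime <- function(C, params) {
  r <- ifelse(bcdMineralLimited(C, params) >= docSupply(params),
              "OCL", "MNL")
  factor(r, levels = c("MNL", "OCL"))
}

#' Ciliate biomass at the MNL/OCL crossover
#'
#' The shift between regimes occurs where the quadratic carbon demand meets
#' the DOC supply ceiling: `Cstar = sqrt(psi / k)`.
#'
#' @param params a [FoodWebParameters-class] object.
#' @return crossover ciliate biomass in nmol-P/L.
#' @export
crossoverCiliateDensity <- function(params) {
  stopifnot(is(params, "FoodWebParameters"))
  sqrt(docSupply(params) / bcdQuadraticCoefficient(params))
}

#' Phosphorus content of a ciliate cell
#'
#' Converts an equivalent spherical diameter to per-cell phosphorus via a
#' volumetric carbon density and Redfield-type C:P stoichiometry:
#' `sigma = (pi/6) d^3 * carbonDensity / carbonMolarMass / molarCtoP`,
#' expressed in nmol-P per cell.  With d = 20 um, 0.13 pg-C/um^3 and
#' C:P = 106 this reproduces the reference value of about 0.00043.
#'
#' @param diameter equivalent spherical diameter (um); may be 0.
#' @param carbonDensity specific carbon content (pg-C/um^3).
#' @param molarCtoP molar carbon-to-phosphorus ratio (dimensionless).
#' @param carbonMolarMass molar mass of carbon (g/mol).
#' @return sigma in nmol-P per cell.
#' @examples
#' ciliatePContent(20)  # ~0.00043 nmol-P per cell
#' @export
ciliatePContent <- function(diameter, carbonDensity = 0.13, molarCtoP = 106,
                            carbonMolarMass = 12.011) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter < 0))
    stop("'diameter' must be non-negative and finite")
  for (nm in c("carbonDensity", "molarCtoP", "carbonMolarMass"))
    stopifNotScalarNumber(get(nm), nm, positive = TRUE)
  volume <- pi / 6 * diameter^3                  # um^3
  pgC <- volume * carbonDensity                  # pg C
  molC <- pgC * 1e-12 / carbonMolarMass          # mol C
  molC / molarCtoP * 1e9                         # nmol P
}

#' Bacterial carbon demand from ciliate cell counts
#'
#' Bridges observational units to the biomass-based theory: ciliate counts
#' in cells/mL are converted to nmol-P/L via `sigma * 1000` (mL to L), the
#' quadratic coefficient is rescaled by the net temperature factor
#' `q10^((temperature - tRef)/10)`, and the DOC supply ceiling `psi` is
#' applied unchanged.
#'
#' @param Ccells ciliate abundance in cells/mL (vectorised, non-negative).
#' @param params a [FoodWebParameters-class] object.
#' @param temperature water temperature in degrees C; defaults to the
#'   parameter set's reference temperature.
#' @return carbon demand in nmol-C/L/h.
#' @export
bcdCells <- function(Ccells, params, temperature = refTemperature(params)) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(Ccells)
  stopifNotScalarNumber(temperature, "temperature")
  C <- Ccells * sigmaCiliate(params) * 1000          # nmol-P/L
  f <- q10(params)^((temperature - refTemperature(params)) / 10)
  pmin(f * bcdQuadraticCoefficient(params) * C^2, docSupply(params))
}

#' Steady-state predictions over a set of ciliate biomasses
#'
#' Evaluates all closed-form steady-state quantities of the pentagon food
#' web at each supplied ciliate abundance.
#'
#' @param C ciliate abundance; biomass in nmol-P/L, or cells/mL when
#'   `cells = TRUE`.
#' @param params a [FoodWebParameters-class] object.
#' @param cells logical; interpret `C` as cell counts (converted through
#'   `sigmaCiliate(params) * 1000`).
#' @param temperature temperature (degrees C) at which rate parameters are
#'   evaluated.
#' @return a `data.frame` with columns `C` (nmol-P/L), `B`, `P` (nmol-P/L),
#'   `mu` (1/h), `bcd` (nmol-C/L/h) and `regime` (factor MNL/OCL).
#' @examples
#' p <- foodWebParameters(yieldBC = 1, psi = 1)
#' steadyState(c(0, 10, 30, 60), p)
#' @export
steadyState <- function(C, params, cells = FALSE,
                        temperature = refTemperature(params)) {
  stopifnot(is(params, "FoodWebParameters"))
  checkCiliate(C)
  pT <- temperatureScale(params, temperature)
  Cb <- if (cells) C * sigmaCiliate(params) * 1000 else C
  data.frame(C = Cb,
             B = prokaryoteBiomass(Cb, pT),
             P = freePhosphate(Cb, pT),
             mu = prokaryoteGrowthRate(Cb, pT),
             bcd = bcd(Cb, pT),
             regime = classifyRegime(Cb, pT))
}
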