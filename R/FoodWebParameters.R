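#' @include AllGenerics.R
NULL

#' FoodWebParameters: rate constants of the pentagon food web
#'
#' Holds the affinities/clearance rates, yields and conversion factors of the
#' five-compartment (pentagon) microbial food web: free phosphate (P),
#' autotrophic flagellates (A), heterotrophic prokaryotes (B), heterotrophic
#' nanoflagellates (H) and ciliates (C).  All biomasses are expressed in
#' phosphorus units (nmol-P/L), so affinities and clearance rates share the
#' unit L/nmol-P/h.
#'
#' @slot alphaB prokaryote affinity for phosphate (L/nmol-P/h).
#' @slot alphaA autotrophic flagellate affinity for phosphate (L/nmol-P/h).
#' @slot alphaH nanoflagellate clearance rate on prokaryotes (L/nmol-P/h).
#' @slot alphaC ciliate clearance rate on flagellates (L/nmol-P/h).
#' @slot yieldH nanoflagellate yield on prokaryotes (nmol-P/nmol-P), in (0, 1].
#' @slot yieldBC prokaryote yield on labile DOC (nmol-P/nmol-C).  No community
#'   consensus value exists; it must be supplied by configuration.
#' @slot sigma phosphorus content per ciliate cell (nmol-P/cell), used to
#'   convert microscopy/FCM cell counts to P-biomass.
#' @slot q10 temperature sensitivity of the rate parameters (dimensionless,
#'   >= 1).
#' @slot tRef reference temperature (degrees C) at which the alphas are given.
#' @slot psi supply rate of labile dissolved organic carbon (nmol-C/L/h); the
#'   ceiling on sustainable bacterial carbon demand.  Must be supplied by
#'   configuration.
#'
#' @seealso [foodWebParameters()], [readFoodWebParameters()],
#'   [temperatureScale()]
#' @export
setClass("FoodWebParameters",
  representation(alphaB = "numeric", alphaA = "numeric", alphaH = "numeric",
                 alphaC = "numeric", yieldH = "numeric", yieldBC = "numeric",
                 sigma = "numeric", q10 = "numeric", tRef = "numeric",
                 psi = "numeric"))

setValidity("FoodWebParameters", function(object) {
  msg <- character()
  num <- c(alphaB = object@alphaB, alphaA = object@alphaA,
           alphaH = object@alphaH, alphaC = object@alphaC,
           yieldH = object@yieldH, yieldBC = object@yieldBC,
           sigma = object@sigma, q10 = object@q10, tRef = object@tRef,
           psi = object@psi)
  if (any(lengths(list(object@alphaB, object@alphaA, object@alphaH,
                       object@alphaC, object@yieldH, object@yieldBC,
                       object@sigma, object@q10, object@tRef,
                       object@psi)) != 1L))
    return("all parameter slots must have length 1")
  if (any(!is.finite(num)))
    msg <- c(msg, "all parameters must be finite")
  pos <- num[c("alphaB", "alphaA", "alphaH", "alphaC", "yieldH", "yieldBC",
               "sigma", "psi")]
  if (any(is.finite(pos) & pos <= 0))
    msg <- c(msg, sprintf("strictly positive value required for: %s",
                          paste(names(pos)[is.finite(pos) & pos <= 0],
                                collapse = ", ")))
  if (is.finite(object@yieldH) && object@yieldH > 1)
    msg <- c(msg, "yieldH must lie in (0, 1]")
  if (is.finite(object@q10) && object@q10 < 1)
    msg <- c(msg, "q10 must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a FoodWebParameters object
#'
#' Default rate values are the reference parameterisation of the pentagon
#' food web at 17 degrees C.  `yieldBC` (prokaryote yield on DOC) and `psi`
#' (labile-DOC supply) have no canonical value and must always be given
#' explicitly.
#'
#' @param alphaB,alphaA,alphaH,alphaC affinities/clearance rates
#'   (L/nmol-P/h).
#' @param yieldH nanoflagellate yield on prokaryotes, in (0, 1].
#' @param yieldBC prokaryote yield on DOC (nmol-P/nmol-C); mandatory.
#' @param sigma P content per ciliate cell (nmol-P/cell).
#' @param q10 temperature sensitivity of the alphas.
#' @param tRef reference temperature (degrees C).
#' @param psi labile-DOC supply rate (nmol-C/L/h); mandatory.
#' @return a validated [FoodWebParameters-class] object.
#' @examples
#' p <- foodWebParameters(yieldBC = 0.006, psi = 4.63)
#' crossoverCiliateDensity(p)
#' @export
foodWebParameters <- function(alphaB = 0.08, alphaA = 0.04, alphaH = 0.0015,
                              alphaC = 0.0005, yieldH = 0.3, yieldBC,
                              sigma = 0.00043, q10 = 1.3, tRef = 17,
                              psi) {
  if (missing(yieldBC))
    stop("'yieldBC' (prokaryote yield on DOC) has no canonical value and ",
         "must be supplied explicitly")
  if (missing(psi))
    stop("'psi' (labile-DOC supply rate) has no canonical value and ",
         "must be supplied explicitly")
  new("FoodWebParameters", alphaB = alphaB, alphaA = alphaA, alphaH = alphaH,
      alphaC = alphaC, yieldH = yieldH, yieldBC = yieldBC, sigma = sigma,
      q10 = q10, tRef = tRef, psi = psi)
}

#' @describeIn FoodWebParameters-class prokaryote phosphate affinity.
#' @param object a `FoodWebParameters` object.
#' @export
setMethod("alphaB", "FoodWebParameters", function(object) object@alphaB)
#' @describeIn FoodWebParameters-class autotroph phosphate affinity.
#' @export
setMethod("alphaA", "FoodWebParameters", function(object) object@alphaA)
#' @describeIn FoodWebParameters-class HNF clearance on prokaryotes.
#' @export
setMethod("alphaH", "FoodWebParameters", function(object) object@alphaH)
#' @describeIn FoodWebParameters-class ciliate clearance on flagellates.
#' @export
setMethod("alphaC", "FoodWebParameters", function(object) object@alphaC)
#' @describeIn FoodWebParameters-class HNF yield on prokaryotes.
#' @export
setMethod("yieldH", "FoodWebParameters", function(object) object@yieldH)
#' @describeIn FoodWebParameters-class prokaryote yield on DOC.
#' @export
setMethod("yieldBC", "FoodWebParameters", function(object) object@yieldBC)
#' @describeIn FoodWebParameters-class P content per ciliate cell.
#' @export
setMethod("sigmaCiliate", "FoodWebParameters", function(object) object@sigma)
#' @describeIn FoodWebParameters-class temperature sensitivity.
#' @export
setMethod("q10", "FoodWebParameters", function(object) object@q10)
#' @describeIn FoodWebParameters-class reference temperature (degrees C).
#' @export
setMethod("refTemperature", "FoodWebParameters", function(object) object@tRef)
#' @describeIn FoodWebParameters-class labile-DOC supply rate psi.
#' @export
setMethod("docSupply", "FoodWebParameters", function(object) object@psi)

#' @describeIn FoodWebParameters-class rescale all alphas by
#'   `q10^((temperature - tRef)/10)`; yields, sigma and psi are unchanged and
#'   `tRef` is moved to the new temperature so the operation composes.
#' @param temperature target temperature (degrees C).
#' @export
setMethod("temperatureScale", "FoodWebParameters",
  function(object, temperature) {
    stopifNotScalarNumber(temperature, "temperature")
    f <- object@q10^((temperature - object@tRef) / 10)
    initialize(object,
               alphaB = object@alphaB * f, alphaA = object@alphaA * f,
               alphaH = object@alphaH * f, alphaC = object@alphaC * f,
               tRef = temperature)
  })

setMethod("show", "FoodWebParameters", function(object) {
  cat("FoodWebParameters (pentagon food web, reference ",
      object@tRef, " degC)\n", sep = "")
  cat(sprintf("  affinities (L/nmol-P/h): alphaB=%g alphaA=%g alphaH=%g alphaC=%g\n",
              object@alphaB, object@alphaA, object@alphaH, object@alphaC))
  cat(sprintf("  yields: yieldH=%g (P/P), yieldBC=%g (nmol-P/nmol-C)\n",
              object@yieldH, object@yieldBC))
  cat(sprintf("  sigma=%g nmol-P/ciliate, Q10=%g, psi=%g nmol-C/L/h\n",
              object@sigma, object@q10, object@psi))
  cat(sprintf("  MNL->OCL crossover: C* = %g nmol-P/L (%g cells/mL)\n",
              crossoverCiliateDensity(object),
              crossoverCiliateDensity(object) / (object@sigma * 1000)))
  invisible(NULL)
})

## ---- parameter file I/O -----------------------------------------------

paramFileKeys <- c(alpha_B = "alphaB", alpha_A = "alphaA", alpha_H = "alphaH",
                   alpha_C = "alphaC", Y_H = "yieldH", Y_BC = "yieldBC",
                   sigma = "sigma", Q10 = "q10", T_ref = "tRef", psi = "psi")

#' Read food-web parameters from a YAML configuration file
#'
#' The file uses the field names of the standard parameter table
#' (`alpha_B`, `alpha_A`, `alpha_H`, `alpha_C`, `Y_H`, `Y_BC`, `sigma`,
#' `Q10`, `T_ref`, `psi`).  `Y_BC` and `psi` are mandatory: the steady-state
#' theory leaves them free, so no default is ever assumed.  Unknown keys are
#' ignored with a warning.
#'
#' @param path path to a YAML file.
#' @return a validated [FoodWebParameters-class] object.
#' @examples
#' f <- system.file("extdata", "params_pentagon.yaml", package = "pentaweb")
#' readFoodWebParameters(f)
#' @export
readFoodWebParameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(paramFileKeys))
  if (length(unknown))
    warning("ignoring unknown parameter key(s): ",
            paste(unknown, collapse = ", "))
  raw <- raw[intersect(names(raw), names(paramFileKeys))]
  for (k in c("Y_BC", "psi"))
    if (is.null(raw[[k]]))
      stop("parameter file must provide '", k, "': the steady-state theory ",
           "leaves it unvalued, so it has to come from configuration")
  args <- stats::setNames(lapply(raw, as.numeric), paramFileKeys[names(raw)])
  do.call(foodWebParameters, args)
}

#' Write food-web parameters to a YAML configuration file
#'
#' @param params a [FoodWebParameters-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFoodWebParameters <- function(params, path) {
  stopifnot(is(params, "FoodWebParameters"))
  vals <- list(alpha_B = params@alphaB, alpha_A = params@alphaA,
               alpha_H = params@alphaH, alpha_C = params@alphaC,
               Y_H = params@yieldH, Y_BC = params@yieldBC,
               sigma = params@sigma, Q10 = params@q10, T_ref = params@tRef,
               psi = params@psi)
  yaml::write_yaml(vals, path, precision = 15L)
  invisible(path)
}
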