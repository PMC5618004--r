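#' @include pentaweb-package.R
NULL

#' @export
setGeneric("alphaB", function(object) standardGeneric("alphaB"))
#' @export
setGeneric("alphaA", function(object) standardGeneric("alphaA"))
#' @export
setGeneric("alphaH", function(object) standardGeneric("alphaH"))
#' @export
setGeneric("alphaC", function(object) standardGeneric("alphaC"))
#' @export
setGeneric("yieldH", function(object) standardGeneric("yieldH"))
#' @export
setGeneric("yieldBC", function(object) standardGeneric("yieldBC"))
#' @export
setGeneric("sigmaCiliate", function(object) standardGeneric("sigmaCiliate"))
#' @export
setGeneric("q10", function(object) standardGeneric("q10"))
#' @export
setGeneric("refTemperature", function(object) standardGeneric("refTemperature"))
#' @export
setGeneric("docSupply", function(object) standardGeneric("docSupply"))

#' Rescale rate parameters to a new temperature
#'
#' @param object an object carrying temperature-sensitive rate parameters.
#' @param temperature target temperature in degrees Celsius.
#' @export
setGeneric("temperatureScale",
           function(object, temperature) standardGeneric("temperatureScale"))

#' @export
setGeneric("bandValues", function(object) standardGeneric("bandValues"))
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @export
setGeneric("bandIds", function(object) standardGeneric("bandIds"))
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @export
setGeneric("ordinationScores", function(object) standardGeneric("ordinationScores"))
#' @export
setGeneric("stressValue", function(object) standardGeneric("stressValue"))
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @export
setGeneric("pseudoF", function(object) standardGeneric("pseudoF"))
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @export
setGeneric("medianP", function(object) standardGeneric("medianP"))
#' @export
setGeneric("pctSignificant", function(object) standardGeneric("pctSignificant"))
#' @export
setGeneric("medianCorrelation", function(object) standardGeneric("medianCorrelation"))
#' @export
setGeneric("nRepeats", function(object) standardGeneric("nRepeats"))
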