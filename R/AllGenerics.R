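#' @include AllClasses.R
NULL

#' @export
setGeneric("spectra", function(object, ...) standardGeneric("spectra"))

#' @export
setGeneric("wavelengths", function(object, ...) standardGeneric("wavelengths"))

#' @export
setGeneric("sampleMeta", function(object, ...) standardGeneric("sampleMeta"))

#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setGeneric("nWavelengths", function(object) standardGeneric("nWavelengths"))

#' @export
setGeneric("uniformSpacing", function(object) standardGeneric("uniformSpacing"))

#' @export
setGeneric("splitByLabel", function(object, label) standardGeneric("splitByLabel"))

#' @export
setGeneric("schemeId", function(object) standardGeneric("schemeId"))

#' @export
setGeneric("schemeSteps", function(object) standardGeneric("schemeSteps"))

#' @export
setGeneric("loadings", function(object, ...) standardGeneric("loadings"))

#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))

#' @export
setGeneric("explainedVariance", function(object, ...) standardGeneric("explainedVariance"))

#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @export
setGeneric("coefVector", function(object) standardGeneric("coefVector"))

#' @export
setGeneric("modelIntercept", function(object) standardGeneric("modelIntercept"))
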