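#' @include AllClasses.R
NULL

#' @export
setGeneric("excitation", function(x) standardGeneric("excitation"))

#' @export
setGeneric("emission", function(x) standardGeneric("emission"))

#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @export
setGeneric("eemUnit", function(x) standardGeneric("eemUnit"))

#' @export
setGeneric("eemMask", function(x) standardGeneric("eemMask"))

#' @export
setGeneric("eemMeta", function(x) standardGeneric("eemMeta"))

#' @export
setGeneric("absorbanceAt", function(x, wavelength) standardGeneric("absorbanceAt"))

#' @export
setGeneric("peakNames", function(x) standardGeneric("peakNames"))

#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @export
setGeneric("peakValues", function(x, peak) standardGeneric("peakValues"))

#' @export
setGeneric("cfuPerMl", function(x) standardGeneric("cfuPerMl"))

#' @export
setGeneric("fractionPercent", function(x) standardGeneric("fractionPercent"))

#' @export
setGeneric("fractionF", function(x) standardGeneric("fractionF"))

#' @export
setGeneric("fTotal", function(x) standardGeneric("fTotal"))
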