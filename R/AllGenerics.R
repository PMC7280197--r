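#' Number of measurements in a scheme or volume
#' @param x an [AcquisitionScheme-class] or [DwiVolume-class]
#' @return integer count of measurements
#' @export
setGeneric("nMeasurements", function(x) standardGeneric("nMeasurements"))

#' b-values of a scheme (s/mm^2)
#' @param x an [AcquisitionScheme-class] or [DwiVolume-class]
#' @return numeric vector of b-values in s/mm^2, one per measurement
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' Logical b0 indicator per measurement
#' @param x an [AcquisitionScheme-class] or [DwiVolume-class]
#' @return logical vector, `TRUE` where a measurement is a b~0 reference
#' @export
setGeneric("isB0", function(x) standardGeneric("isB0"))

#' Measurement table of a scheme
#' @param x an [AcquisitionScheme-class]
#' @return the measurement data.frame
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' Extract a parameter map
#' @param x a [ParameterMaps-class]
#' @param name parameter name, e.g. "fSphere"
#' @return 3-D numeric array (`NA` outside the fitted mask)
#' @export
setGeneric("parameterMap", function(x, name) standardGeneric("parameterMap"))
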