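#' Accessor generics
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("optics", function(x) standardGeneric("optics"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname accessors
#' @export
setGeneric("phaseMap", function(x) standardGeneric("phaseMap"))

#' @rdname accessors
#' @export
setGeneric("support", function(x) standardGeneric("support"))

#' @rdname accessors
#' @export
setGeneric("holoIntensity", function(x) standardGeneric("holoIntensity"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("segmentValues", function(x) standardGeneric("segmentValues"))

#' @rdname accessors
#' @export
setGeneric("statValue", function(x) standardGeneric("statValue"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("decision", function(x) standardGeneric("decision"))

#' @rdname accessors
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

setMethod("optics", "ComplexField", function(x) x@optics)
setMethod("optics", "PhaseObject", function(x) x@optics)
setMethod("optics", "Hologram", function(x) x@optics)
setMethod("fieldValues", "ComplexField", function(x) x@values)
setMethod("amplitude", "ComplexField", function(x) Mod(x@values))
setMethod("phaseMap", "ComplexField", function(x) Arg(x@values))
setMethod("phaseMap", "PhaseObject", function(x) x@phaseMap)
setMethod("support", "PhaseObject", function(x) x@support)
setMethod("holoIntensity", "Hologram", function(x) x@intensity)
setMethod("maskMatrix", "TargetMask", function(x) x@mask)
setMethod("segmentValues", "SamplingSegment", function(x) x@values)
setMethod("statValue", "VarianceRatioResult", function(x) x@statistic)
setMethod("statValue", "EcdfTestResult", function(x) x@statistic)
setMethod("pValue", "VarianceRatioResult", function(x) x@pValue)
setMethod("pValue", "EcdfTestResult", function(x) x@pValue)
setMethod("decision", "VarianceRatioResult", function(x) x@decision)
setMethod("decision", "EcdfTestResult", function(x) x@decision)
setMethod("nullStats", "EcdfTestResult", function(x) x@nullStatistics)
setMethod("auc", "RocResult", function(x) x@auc)
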