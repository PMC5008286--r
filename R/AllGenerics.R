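#' @rdname referenceAmplicon
#' @export
setGeneric("ampliconSequence", function(x) standardGeneric("ampliconSequence"))

#' @rdname referenceAmplicon
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' @rdname referenceAmplicon
#' @export
setGeneric("nonCpgCPositions",
           function(x) standardGeneric("nonCpgCPositions"))

#' @rdname CloneMatrix-accessors
#' @export
setGeneric("cloneCalls", function(x) standardGeneric("cloneCalls"))

#' @rdname CloneMatrix-accessors
#' @export
setGeneric("conversionRates", function(x) standardGeneric("conversionRates"))

#' @rdname CloneMatrix-accessors
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname CloneMatrix-accessors
#' @export
setGeneric("flaggedClones",
           function(x, minConversion = 0.95) standardGeneric("flaggedClones"))

#' @rdname referenceRange
#' @export
setGeneric("rangeTable", function(x) standardGeneric("rangeTable"))

#' @rdname referenceRange
#' @export
setGeneric("indexThreshold", function(x) standardGeneric("indexThreshold"))
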