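#' @export
setGeneric("featureId", function(x) standardGeneric("featureId"))

#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' @export
setGeneric("rtMinutes", function(x) standardGeneric("rtMinutes"))

#' @export
setGeneric("peakMatrix", function(x) standardGeneric("peakMatrix"))

#' @export
setGeneric("peakCount", function(x) standardGeneric("peakCount"))

#' @export
setGeneric("similarityScore", function(x) standardGeneric("similarityScore"))

#' @export
setGeneric("nMatched", function(x) standardGeneric("nMatched"))

#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @export
setGeneric("passingFeatures", function(x) standardGeneric("passingFeatures"))
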