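#' @export
setGeneric("constituents", function(x) standardGeneric("constituents"))
#' @export
setGeneric("poolRatios", function(x) standardGeneric("poolRatios"))
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @export
setGeneric("lineId", function(x) standardGeneric("lineId"))
#' @export
setGeneric("catalogCalls", function(x) standardGeneric("catalogCalls"))
#' @export
setGeneric("catalogLines", function(x) standardGeneric("catalogLines"))
#' @export
setGeneric("truthRecords", function(x) standardGeneric("truthRecords"))
#' @export
setGeneric("backgroundAlleles", function(x) standardGeneric("backgroundAlleles"))
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))
#' @export
setGeneric("readRecords", function(x, ...) standardGeneric("readRecords"))
#' @export
setGeneric("alleleCounts", function(x, ...) standardGeneric("alleleCounts"))
#' @export
setGeneric("depthTable", function(x) standardGeneric("depthTable"))
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setGeneric("meanDepth", function(x) standardGeneric("meanDepth"))
#' @export
setGeneric("filterCounts", function(x) standardGeneric("filterCounts"))
#' @export
setGeneric("filterRates", function(x) standardGeneric("filterRates"))
#' @export
setGeneric("errorFreqs", function(x) standardGeneric("errorFreqs"))
#' @export
setGeneric("contaminationEstimate",
           function(x) standardGeneric("contaminationEstimate"))
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @export
setGeneric("sensitivityBins", function(x) standardGeneric("sensitivityBins"))
#' @export
setGeneric("concordanceClasses",
           function(x) standardGeneric("concordanceClasses"))
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @export
setGeneric("truthData", function(x) standardGeneric("truthData"))
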