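NULL

#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @export
setGeneric("bValue", function(x) standardGeneric("bValue"))

#' @export
setGeneric("nDirections", function(x) standardGeneric("nDirections"))

#' @export
setGeneric("minPairwiseAngle", function(x) standardGeneric("minPairwiseAngle"))

#' @export
setGeneric("fiberAxes", function(x) standardGeneric("fiberAxes"))

#' @export
setGeneric("fiberWeights", function(x) standardGeneric("fiberWeights"))

#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @export
setGeneric("subjectSignals", function(x, d) standardGeneric("subjectSignals"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("trueAxes", function(x) standardGeneric("trueAxes"))

#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))

#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @export
setGeneric("templateSignals", function(x) standardGeneric("templateSignals"))

#' @export
setGeneric("convergenceTrace", function(x) standardGeneric("convergenceTrace"))

#' @export
setGeneric("iterationsUsed", function(x) standardGeneric("iterationsUsed"))

#' @export
setGeneric("peakAxes", function(x) standardGeneric("peakAxes"))

#' @export
setGeneric("peakValues", function(x) standardGeneric("peakValues"))

#' @export
setGeneric("momentMagnitudes", function(x) standardGeneric("momentMagnitudes"))

#' @export
setGeneric("momentOrder", function(x) standardGeneric("momentOrder"))
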