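#' @import methods
NULL

#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))

#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @export
setGeneric("firingRate", function(x) standardGeneric("firingRate"))

#' @export
setGeneric("baselineStats", function(x) standardGeneric("baselineStats"))

#' @export
setGeneric("degenerateUnits", function(x) standardGeneric("degenerateUnits"))

#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @export
setGeneric("accuracySEM", function(x) standardGeneric("accuracySEM"))

#' @export
setGeneric("chanceLevel", function(x) standardGeneric("chanceLevel"))

#' @export
setGeneric("maxAccuracy", function(x) standardGeneric("maxAccuracy"))

#' @export
setGeneric("slopeEstimate", function(x) standardGeneric("slopeEstimate"))

#' @export
setGeneric("slopeSE", function(x) standardGeneric("slopeSE"))

#' @export
setGeneric("interceptEstimate", function(x) standardGeneric("interceptEstimate"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
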