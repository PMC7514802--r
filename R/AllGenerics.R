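#' @rdname GrayHistogram-class
#' @param object a `GrayHistogram`
#' @export
setGeneric("histCounts", function(object) standardGeneric("histCounts"))

#' @rdname GrayHistogram-class
#' @export
setGeneric("histProbs", function(object) standardGeneric("histProbs"))

#' @rdname GrayHistogram-class
#' @export
setGeneric("totalPixels", function(object) standardGeneric("totalPixels"))

#' @rdname OptimizerResult-class
#' @param object an `OptimizerResult` or `SegmentationResult`
#' @export
setGeneric("bestThresholds", function(object) standardGeneric("bestThresholds"))

#' @rdname OptimizerResult-class
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))

#' @rdname OptimizerResult-class
#' @export
setGeneric("convergence", function(object) standardGeneric("convergence"))

#' @rdname OptimizerResult-class
#' @export
setGeneric("evaluations", function(object) standardGeneric("evaluations"))

#' @rdname SegmentationResult-class
#' @param object a `SegmentationResult`
#' @export
setGeneric("channelThresholds", function(object) standardGeneric("channelThresholds"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("segmentedImage", function(object) standardGeneric("segmentedImage"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("channelFitness", function(object) standardGeneric("channelFitness"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("totalFitness", function(object) standardGeneric("totalFitness"))
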