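#' @rdname GrayHistogram-class
#' @export
setMethod("histCounts", "GrayHistogram", function(object) object@counts)

#' @rdname GrayHistogram-class
#' @export
setMethod("histProbs", "GrayHistogram", function(object) object@probs)

#' @rdname GrayHistogram-class
#' @export
setMethod("totalPixels", "GrayHistogram", function(object) object@totalPixels)

setMethod("show", "GrayHistogram", function(object) {
    occ <- which(object@counts > 0L) - 1L
    cat("GrayHistogram:", object@totalPixels, "pixels,",
        length(occ), "occupied levels in [",
        min(occ), ",", max(occ), "]\n")
})

#' @rdname OptimizerResult-class
#' @export
setMethod("bestThresholds", "OptimizerResult", function(object) object@bestThresholds)

#' @rdname OptimizerResult-class
#' @export
setMethod("bestFitness", "OptimizerResult", function(object) object@bestFitness)

#' @rdname OptimizerResult-class
#' @export
setMethod("convergence", "OptimizerResult", function(object) object@history)

#' @rdname OptimizerResult-class
#' @export
setMethod("evaluations", "OptimizerResult", function(object) object@evaluations)

setMethod("show", "OptimizerResult", function(object) {
    cat("OptimizerResult (", object@algorithm, "): K=",
        length(object@bestThresholds), "\n", sep = "")
    cat("  best thresholds:", paste(object@bestThresholds, collapse = ", "), "\n")
    cat("  best fitness:   ", format(object@bestFitness, digits = 8), "\n")
    cat("  evaluations:    ", object@evaluations,
        " (WOA moves ", object@woaMoves, ", DE moves ", object@deMoves, ")\n",
        sep = "")
})

#' @rdname SegmentationResult-class
#' @export
setMethod("channelThresholds", "SegmentationResult", function(object) object@thresholds)

#' @rdname SegmentationResult-class
#' @export
setMethod("segmentedImage", "SegmentationResult", function(object) object@segmented)

#' @rdname SegmentationResult-class
#' @export
setMethod("channelFitness", "SegmentationResult", function(object) object@perChannelFitness)

#' @rdname SegmentationResult-class
#' @export
setMethod("totalFitness", "SegmentationResult", function(object) object@totalFitness)

setMethod("show", "SegmentationResult", function(object) {
    nc <- length(object@thresholds)
    cat("SegmentationResult: ", nc, " channel(s), K=", object@K,
        ", objective=", object@objective, "\n", sep = "")
    for (ch in seq_len(nc)) {
        cat("  channel ", ch, ": [",
            paste(object@thresholds[[ch]], collapse = ", "),
            "]  fitness=", format(object@perChannelFitness[ch], digits = 8),
            "\n", sep = "")
    }
    cat("  total fitness:", format(object@totalFitness, digits = 8), "\n")
})
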