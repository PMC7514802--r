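#' @import methods
NULL

#' Gray-level histogram of one 8-bit image channel
#'
#' A 256-bin histogram over the gray levels 0..255: raw counts, the
#' normalized probabilities \eqn{p_j = counts_j / totalPixels}, and the
#' pixel total. All thresholding objectives in this package are functions
#' of this object alone, never of the pixel array.
#'
#' @slot counts integer vector of length 256, nonnegative per-level tallies.
#' @slot probs numeric vector of length 256 summing to 1.
#' @slot totalPixels positive integer, the number of pixels tallied.
#'
#' @seealso [grayHistogram()] to build one from a pixel matrix,
#'   [kapurEntropy()], [otsuVariance()].
#' @exportClass GrayHistogram
setClass("GrayHistogram",
    representation(
        counts = "integer",
        probs = "numeric",
        totalPixels = "integer"
    )
)

setValidity("GrayHistogram", function(object) {
    msg <- character()
    if (length(object@counts) != 256L)
        msg <- c(msg, "'counts' must have length 256")
    if (length(object@probs) != 256L)
        msg <- c(msg, "'probs' must have length 256")
    if (any(object@counts < 0L))
        msg <- c(msg, "'counts' must be nonnegative")
    if (length(object@totalPixels) != 1L || object@totalPixels <= 0L)
        msg <- c(msg, "'totalPixels' must be a single positive integer")
    if (any(object@probs < 0))
        msg <- c(msg, "'probs' must be nonnegative")
    if (abs(sum(object@probs) - 1) > 1e-12)
        msg <- c(msg, "'probs' must sum to 1 (within 1e-12)")
    if (length(msg) == 0L &&
        max(abs(object@probs - object@counts / object@totalPixels)) > 1e-12)
        msg <- c(msg, "'probs' must equal counts/totalPixels")
    if (length(msg)) msg else TRUE
})

#' Search parameters of the threshold optimizers
#'
#' Bundles the population size, iteration budget, differential-evolution
#' rates, whale-optimization spiral constant, search bounds and the seed
#' of the single RNG stream driving one optimizer run.
#'
#' @slot nAgents integer, population size (>= 4 so DE mutation can draw
#'   three partners distinct from the target).
#' @slot maxIter integer, number of iterations.
#' @slot CR numeric in [0,1], DE crossover probability.
#' @slot SF positive numeric, DE mutation scaling factor.
#' @slot b numeric, logarithmic-spiral shape constant of the WOA
#'   bubble-net move.
#' @slot seed integer seed (NA for "leave the RNG stream alone").
#' @slot lower,upper numeric search-space bounds (threshold gray levels).
#'
#' @seealso [optimizerConfig()]
#' @exportClass OptimizerConfig
setClass("OptimizerConfig",
    representation(
        nAgents = "integer",
        maxIter = "integer",
        CR = "numeric",
        SF = "numeric",
        b = "numeric",
        seed = "integer",
        lower = "numeric",
        upper = "numeric"
    )
)

setValidity("OptimizerConfig", function(object) {
    msg <- character()
    if (object@nAgents < 4L)
        msg <- c(msg, "'nAgents' must be >= 4 (DE needs 3 partners plus the target)")
    if (object@maxIter < 1L)
        msg <- c(msg, "'maxIter' must be >= 1")
    if (object@CR < 0 || object@CR > 1)
        msg <- c(msg, "'CR' must lie in [0, 1]")
    if (object@SF <= 0)
        msg <- c(msg, "'SF' must be positive")
    if (object@lower >= object@upper)
        msg <- c(msg, "'lower' must be < 'upper'")
    if (length(msg)) msg else TRUE
})

#' Result of one optimizer run
#'
#' Best decoded threshold vector, its fitness, the best-so-far convergence
#' history (one entry per iteration, non-decreasing), the number of
#' objective evaluations spent, and instrumentation counters saying how
#' many agent updates went through the whale-optimization branch versus
#' the differential-evolution branch.
#'
#' @slot bestThresholds integer vector, strictly increasing thresholds in
#'   [1, 255].
#' @slot bestFitness numeric, objective value of `bestThresholds`.
#' @slot history numeric vector of length `maxIter`, best-so-far fitness
#'   after each iteration.
#' @slot evaluations integer, objective evaluations performed.
#' @slot algorithm character, one of "woa_de", "woa", "de".
#' @slot woaMoves,deMoves integer branch counters.
#'
#' @seealso [optimizeThresholds()]
#' @exportClass OptimizerResult
setClass("OptimizerResult",
    representation(
        bestThresholds = "integer",
        bestFitness = "numeric",
        history = "numeric",
        evaluations = "integer",
        algorithm = "character",
        woaMoves = "integer",
        deMoves = "integer"
    )
)

setValidity("OptimizerResult", function(object) {
    msg <- character()
    if (length(object@history) > 0L) {
        if (any(diff(object@history) < 0))
            msg <- c(msg, "'history' must be non-decreasing")
        if (object@bestFitness != object@history[length(object@history)])
            msg <- c(msg, "'bestFitness' must equal the last history entry")
    }
    if (is.unsorted(object@bestThresholds, strictly = TRUE))
        msg <- c(msg, "'bestThresholds' must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Segmentation of a grayscale or RGB image
#'
#' Per-channel optimal thresholds, the reconstructed (class-mean) image,
#' and the per-channel and total objective values. For an RGB input the
#' optimizer runs once per color component; `totalFitness` is the sum of
#' the per-channel values (per-channel values are always retained).
#'
#' @slot thresholds list of integer threshold vectors, one per channel.
#' @slot segmented numeric array, same shape as the input, gray levels in
#'   [0, 255]; at most K+1 distinct values per channel.
#' @slot perChannelFitness numeric vector, objective value per channel.
#' @slot totalFitness numeric, sum of per-channel fitness.
#' @slot objective character, "kapur" or "otsu".
#' @slot K integer, number of thresholds per channel.
#'
#' @seealso [thresholdImage()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
    representation(
        thresholds = "list",
        segmented = "array",
        perChannelFitness = "numeric",
        totalFitness = "numeric",
        objective = "character",
        K = "integer"
    )
)

setValidity("SegmentationResult", function(object) {
    msg <- character()
    if (length(object@thresholds) != length(object@perChannelFitness))
        msg <- c(msg, "one fitness per channel threshold vector required")
    if (abs(object@totalFitness - sum(object@perChannelFitness)) > 1e-8)
        msg <- c(msg, "'totalFitness' must be the sum of per-channel fitness")
    if (!object@objective %in% c("kapur", "otsu"))
        msg <- c(msg, "'objective' must be \"kapur\" or \"otsu\"")
    if (length(msg)) msg else TRUE
})
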