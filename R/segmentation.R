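## round-half-up, used everywhere a gray level is produced
.roundHalfUp <- function(x) floor(x + 0.5)

.validateImageArray <- function(image) {
    if (!is.numeric(image))
        stop("image must be numeric")
    d <- dim(image)
    if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3L] == 3L)))
        stop("image must be an MxN matrix or an MxNx3 array")
    if (length(image) == 0L)
        stop("image is empty")
    if (anyNA(image) || any(image < 0 | image > 255) || any(image != round(image)))
        stop("image values must be integer gray levels in [0, 255]")
    invisible(image)
}

.nChannels <- function(image) if (length(dim(image)) == 3L) 3L else 1L

.getChannel <- function(image, ch) {
    if (length(dim(image)) == 3L) image[, , ch] else image
}

#' Read an 8-bit image file into a gray-level array
#'
#' Reads PNG, JPEG or TIFF through EBImage and returns an integer-valued
#' array on the 0..255 scale: an MxN matrix for grayscale or an MxNx3
#' array for color. Inputs with a bit depth above 8 are rejected (the
#' whole pipeline is defined on 256 gray levels).
#'
#' @param path image file path.
#' @return numeric matrix or MxNx3 array of integers in \[0, 255\].
#' @export
readImageArray <- function(path) {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    d <- dim(a)
    if (length(d) == 3L) {
        if (d[3L] < 3L) a <- a[, , 1L] else a <- a[, , 1:3]
    }
    v <- a * 255
    if (max(abs(v - round(v))) > 1e-6)
        stop("only 8-bit images are supported (256 gray levels)")
    v <- round(v)
    ## EBImage stores x (columns) first; transpose to rows x columns
    if (length(dim(v)) == 3L)
        aperm(v, c(2L, 1L, 3L))
    else
        t(v)
}

#' Write a gray-level array as an image file
#'
#' @param image MxN matrix or MxNx3 array of integers in \[0, 255\].
#' @param path output path; the extension picks the format (png, jpeg,
#'   tiff).
#' @return the path, invisibly.
#' @export
writeImageArray <- function(image, path) {
    .validateImageArray(image)
    if (length(dim(image)) == 3L) {
        a <- aperm(image, c(2L, 1L, 3L)) / 255
        img <- EBImage::Image(a, colormode = "Color")
    } else {
        img <- EBImage::Image(t(image) / 255, colormode = "Grayscale")
    }
    EBImage::writeImage(img, path)
    invisible(path)
}

#' Reconstruct one channel from its threshold partition
#'
#' Every pixel falling in the class \[th_i, th_{i+1}) is replaced by the
#' rounded mean gray level of that class's pixels, which minimizes the
#' within-class squared error of the reconstruction. Empty classes
#' contribute no output level, so the result has at most K+1 distinct
#' values.
#'
#' @param channel MxN matrix of integers in \[0, 255\].
#' @param th threshold vector (see [validateThresholds()]).
#' @return matrix of the same shape with class-mean gray levels.
#' @examples
#' segmentChannel(matrix(c(10, 20, 200, 220), 4, 1), 128)
#' @export
segmentChannel <- function(channel, th) {
    if (is.null(dim(channel))) dim(channel) <- c(length(channel), 1L)
    .validateImageArray(channel)
    th <- validateThresholds(th)
    cls <- findInterval(channel, th)   # 0..K, class of each pixel
    out <- channel
    for (k in unique(as.vector(cls))) {
        idx <- cls == k
        out[idx] <- .roundHalfUp(mean(channel[idx]))
    }
    out
}

#' Multilevel thresholding of a grayscale or RGB image
#'
#' Runs the chosen optimizer once per channel to find the K thresholds
#' maximizing the objective on that channel's histogram, then rebuilds
#' the image with class-mean gray levels. For RGB the three components
#' are processed independently with channel seeds seed, seed+1, seed+2
#' derived from the configured seed, so one seed fixes the whole run.
#'
#' @param image MxN matrix (grayscale) or MxNx3 array (RGB), integers in
#'   \[0, 255\].
#' @param K number of thresholds per channel.
#' @param kind objective, "kapur" (entropy, default) or "otsu"
#'   (between-class variance).
#' @param config an [OptimizerConfig-class].
#' @param algorithm "woa_de", "woa" or "de".
#' @return a [SegmentationResult-class].
#' @examples
#' img <- generateImage(rbind(c(60, 8, 0.5), c(190, 8, 0.5)),
#'                      size = c(32, 32), seed = 1)
#' res <- thresholdImage(img, K = 1,
#'     config = optimizerConfig(nAgents = 10, maxIter = 20, seed = 1))
#' channelThresholds(res)
#' @export
thresholdImage <- function(image, K, kind = c("kapur", "otsu"),
                           config = optimizerConfig(),
                           algorithm = c("woa_de", "woa", "de")) {
    kind <- match.arg(kind)
    algorithm <- match.arg(algorithm)
    .validateImageArray(image)
    nch <- .nChannels(image)
    objFun <- .objectiveFun(kind)
    thresholds <- vector("list", nch)
    fitness <- numeric(nch)
    segmented <- image
    for (ch in seq_len(nch)) {
        channel <- .getChannel(image, ch)
        hist <- grayHistogram(channel)
        chConfig <- config
        if (!is.na(config@seed))
            chConfig@seed <- config@seed + ch - 1L
        res <- optimizeThresholds(function(th) objFun(hist, th), K,
                                  chConfig, algorithm)
        thresholds[[ch]] <- bestThresholds(res)
        fitness[ch] <- bestFitness(res)
        seg <- segmentChannel(channel, thresholds[[ch]])
        if (nch == 3L) segmented[, , ch] <- seg else segmented <- seg
    }
    new("SegmentationResult",
        thresholds = thresholds,
        segmented = segmented,
        perChannelFitness = fitness,
        totalFitness = sum(fitness),
        objective = kind,
        K = as.integer(K))
}
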