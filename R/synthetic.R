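#' Generate a synthetic image with a multimodal gray-level histogram
#'
#' Each pixel is drawn from a Gaussian mixture over the gray axis: a
#' mode is picked with probability proportional to its weight, a value
#' is drawn from Normal(mean, sd), then rounded half-up and clipped to
#' \[0, 255\]. This emulates the multimodal histograms of natural,
#' satellite and MR test images while keeping every test offline and
#' reproducible. A 3-channel image uses per-channel seeds seed, seed+1,
#' seed+2.
#'
#' @param modes numeric matrix (or coercible) with one row per mode and
#'   columns mean (in \[0, 255\]), sd (> 0), weight (> 0; normalized
#'   internally).
#' @param size c(M, N) image size in pixels.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   image.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @return MxN matrix or MxNx3 array of integers in \[0, 255\].
#' @examples
#' img <- generateImage(rbind(c(50, 1, 0.5), c(200, 1, 0.5)),
#'                      size = c(64, 64), seed = 7)
#' range(img)
#' @export
generateImage <- function(modes, size, seed, channels = 1) {
    modes <- as.matrix(modes)
    if (ncol(modes) != 3L || nrow(modes) < 1L)
        stop("modes must have rows of (mean, sd, weight)")
    if (any(modes[, 1L] < 0 | modes[, 1L] > 255))
        stop("mode means must lie in [0, 255]")
    if (any(modes[, 2L] < 0))
        stop("mode sds must be nonnegative")
    if (any(modes[, 3L] <= 0))
        stop("mode weights must be positive")
    if (!channels %in% c(1, 3))
        stop("channels must be 1 or 3")
    if (length(size) != 2L || any(size < 1))
        stop("size must be c(M, N)")
    wts <- modes[, 3L] / sum(modes[, 3L])
    npix <- as.integer(size[1L]) * as.integer(size[2L])
    drawChannel <- function(s) {
        .withSeed(s, function() {
            comp <- sample.int(nrow(modes), npix, replace = TRUE, prob = wts)
            v <- stats::rnorm(npix, mean = modes[comp, 1L],
                              sd = modes[comp, 2L])
            matrix(pmin(pmax(.roundHalfUp(v), 0), 255),
                   nrow = size[1L], ncol = size[2L])
        })
    }
    if (channels == 1)
        drawChannel(seed)
    else
        array(c(drawChannel(seed), drawChannel(seed + 1L),
                drawChannel(seed + 2L)),
              dim = c(size[1L], size[2L], 3L))
}

#' Random multimodal mixture specification
#'
#' Draws a mixture with the given number of well-spread modes: means on
#' a jittered regular grid over \[20, 235\], sds uniform in \[5, 18\],
#' weights uniform in \[0.5, 1.5\] (normalized at image generation).
#' Convenient for seeding batteries of heterogeneous test histograms.
#'
#' @param nModes number of modes (>= 1).
#' @param seed integer seed.
#' @return a modes matrix suitable for [generateImage()].
#' @export
randomMixture <- function(nModes, seed) {
    if (nModes < 1L) stop("nModes must be >= 1")
    .withSeed(seed, function() {
        centers <- seq(20, 235, length.out = nModes + 2L)[2:(nModes + 1L)]
        means <- pmin(pmax(centers + stats::runif(nModes, -15, 15), 0), 255)
        cbind(mean = means,
              sd = stats::runif(nModes, 5, 18),
              weight = stats::runif(nModes, 0.5, 1.5))
    })
}

#' Corrupt an image with additive Gaussian noise
#'
#' Noise is parameterized on the unit intensity scale, matching how
#' noise variances such as 0.00625..0.1 are quoted for 8-bit test
#' images: pixel' = clip(round(pixel + 255 n), 0, 255) with
#' n ~ Normal(mean, variance). Variance 0 returns the input unchanged.
#'
#' @param image integer-valued image array on the 0..255 scale.
#' @param mean noise mean on the unit scale (default 0).
#' @param variance noise variance on the unit scale (>= 0).
#' @param seed integer seed, or NA to use the current RNG state.
#' @return the corrupted image, same shape.
#' @export
addGaussianNoise <- function(image, mean = 0, variance, seed = NA) {
    .validateImageArray(image)
    if (!is.numeric(variance) || length(variance) != 1L || variance < 0)
        stop("variance must be a single nonnegative number")
    if (variance == 0)
        return(image)
    .withSeed(seed, function() {
        n <- stats::rnorm(length(image), mean = mean, sd = sqrt(variance))
        out <- pmin(pmax(.roundHalfUp(image + 255 * n), 0), 255)
        dim(out) <- dim(image)
        out
    })
}
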