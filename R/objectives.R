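#' Build the 256-bin gray-level histogram of one channel
#'
#' Tallies the gray levels 0..255 of an integer-valued channel and
#' normalizes by the pixel count. This histogram is the sole input to
#' both thresholding objectives.
#'
#' @param channel numeric or integer matrix (or vector) with values in
#'   \[0, 255\]. Values must be whole numbers.
#' @return a [GrayHistogram-class] object.
#' @examples
#' h <- grayHistogram(matrix(c(0, 1, 2, 3), 2, 2))
#' histProbs(h)[1:4]
#' @export
grayHistogram <- function(channel) {
    x <- as.vector(channel)
    if (length(x) == 0L)
        stop("channel is empty")
    if (anyNA(x))
        stop("channel contains NA values")
    if (any(x < 0 | x > 255))
        stop("channel values must lie in [0, 255]")
    if (any(x != round(x)))
        stop("channel values must be integer gray levels")
    counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
    n <- length(x)
    new("GrayHistogram",
        counts = counts,
        probs = counts / n,
        totalPixels = as.integer(n))
}

#' Validate a multilevel threshold vector
#'
#' Thresholds th_1 < ... < th_K must be strictly increasing integers in
#' \[1, 255\]. They induce the K+1 half-open classes \[0, th_1),
#' \[th_1, th_2), ..., \[th_K, 256).
#'
#' @param th integer vector of thresholds.
#' @return the thresholds as an integer vector, invisibly unchanged.
#' @export
validateThresholds <- function(th) {
    if (length(th) == 0L)
        stop("at least one threshold is required")
    if (anyNA(th))
        stop("thresholds contain NA")
    if (any(th != round(th)))
        stop("thresholds must be integers")
    th <- as.integer(th)
    if (any(th < 1L | th > 255L))
        stop("thresholds must lie in [1, 255]")
    if (is.unsorted(th, strictly = TRUE))
        stop("thresholds must be strictly increasing")
    th
}

## class boundaries: c(0, th, 256) -> K+1 half-open classes
.classEdges <- function(th) c(0L, th, 256L)

#' Kapur's entropy of a threshold partition
#'
#' Sum over classes of the Shannon entropy (in nats) of the normalized
#' within-class gray-level distribution:
#' \deqn{H = \sum_i H_i,\qquad
#'       H_i = -\sum_{j \in class_i} \frac{p_j}{\omega_i}
#'             \ln\frac{p_j}{\omega_i},\qquad
#'       \omega_i = \sum_{j \in class_i} p_j.}
#' Bins with \eqn{p_j = 0} contribute nothing (0 ln 0 := 0) and empty
#' classes (\eqn{\omega_i = 0}) contribute 0, keeping the objective
#' finite everywhere. Maximizing H favors partitions whose classes each
#' carry as much information as possible.
#'
#' @param hist a [GrayHistogram-class].
#' @param th threshold vector (see [validateThresholds()]).
#' @return nonnegative entropy in nats.
#' @examples
#' h <- grayHistogram(matrix(c(0, 1, 2, 3), 2, 2))
#' kapurEntropy(h, 2)  # 2*log(2)
#' @export
kapurEntropy <- function(hist, th) {
    stopifnot(is(hist, "GrayHistogram"))
    th <- validateThresholds(th)
    p <- hist@probs
    plogp <- ifelse(p > 0, p * log(p), 0)
    Pc <- c(0, cumsum(p))
    Ec <- c(0, cumsum(plogp))
    edges <- .classEdges(th)
    H <- 0
    for (i in seq_len(length(edges) - 1L)) {
        lo <- edges[i]; hi <- edges[i + 1L]
        w <- Pc[hi + 1L] - Pc[lo + 1L]
        if (w > 0) {
            s <- Ec[hi + 1L] - Ec[lo + 1L]   # sum p log p over the class
            H <- H + (log(w) - s / w)
        }
    }
    H
}

#' Otsu between-class variance of a threshold partition
#'
#' The multilevel between-class variance
#' \deqn{\sigma_B^2 = \sum_i \omega_i (\mu_i - \mu_T)^2}
#' with class probabilities \eqn{\omega_i}, class means \eqn{\mu_i} and
#' global mean \eqn{\mu_T}. Empty classes contribute 0. Maximizing it
#' separates class means as far as the histogram allows; it never
#' exceeds the total histogram variance.
#'
#' @inheritParams kapurEntropy
#' @return nonnegative between-class variance (gray-level units squared).
#' @export
otsuVariance <- function(hist, th) {
    stopifnot(is(hist, "GrayHistogram"))
    th <- validateThresholds(th)
    p <- hist@probs
    lev <- 0:255
    Pc <- c(0, cumsum(p))
    Mc <- c(0, cumsum(p * lev))
    muT <- Mc[257L]
    edges <- .classEdges(th)
    v <- 0
    for (i in seq_len(length(edges) - 1L)) {
        lo <- edges[i]; hi <- edges[i + 1L]
        w <- Pc[hi + 1L] - Pc[lo + 1L]
        if (w > 0) {
            mu <- (Mc[hi + 1L] - Mc[lo + 1L]) / w
            v <- v + w * (mu - muT)^2
        }
    }
    v
}

#' Look up an objective function by name
#'
#' @param kind "kapur" or "otsu".
#' @return function of (hist, th).
#' @keywords internal
.objectiveFun <- function(kind) {
    kind <- match.arg(kind, c("kapur", "otsu"))
    if (kind == "kapur") kapurEntropy else otsuVariance
}

#' Exhaustive-search optimum of a thresholding objective
#'
#' Enumerates every strictly increasing threshold vector in \[1, 255\]
#' and returns the global maximizer; ties broken by the
#' lexicographically smallest vector. Used as the ground-truth oracle
#' for the metaheuristics; the enumeration runs in compiled code, so
#' only K <= 3 is permitted (C(255, 3) ~ 2.7 million candidates).
#'
#' @inheritParams kapurEntropy
#' @param K number of thresholds, 1 to 3.
#' @param kind objective, "kapur" or "otsu".
#' @return list with elements `thresholds` (integer vector) and
#'   `fitness` (numeric).
#' @examples
#' h <- grayHistogram(matrix(c(0, 1, 2, 3), 2, 2))
#' bruteForceOptimum(h, 1, "kapur")
#' @export
bruteForceOptimum <- function(hist, K, kind = c("kapur", "otsu")) {
    stopifnot(is(hist, "GrayHistogram"))
    kind <- match.arg(kind)
    if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 1L)
        stop("K must be a positive integer")
    if (K > 3L)
        stop("exhaustive search is limited to K <= 3")
    res <- brute_force_cpp(hist@probs, as.integer(K), kind == "kapur")
    list(thresholds = as.integer(res$thresholds), fitness = res$fitness)
}

#' Write a histogram as CSV (bin, count, prob)
#'
#' @param hist a [GrayHistogram-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeHistogramCSV <- function(hist, path) {
    stopifnot(is(hist, "GrayHistogram"))
    df <- data.frame(bin = 0:255, count = hist@counts, prob = hist@probs)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
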