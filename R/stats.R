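#' Wilcoxon rank-sum test (two-sided)
#'
#' Two-sample location test on midranks. For small samples (both sizes
#' below 10) the p-value is computed by exhaustive enumeration of all
#' rank assignments, so ties are handled exactly; larger samples use
#' the normal approximation with tie correction and continuity
#' correction. The decision flag applies the 5% significance level.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `statistic` (rank sum of `a`), `p.value`, and
#'   `reject` (TRUE iff p < 0.05).
#' @examples
#' rankSumTest(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1 (exact, 2/20 tails)
#' @export
rankSumTest <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L)
        stop("both samples must be nonempty")
    if (anyNA(a) || anyNA(b))
        stop("samples must not contain NA")
    n1 <- length(a); n2 <- length(b); N <- n1 + n2
    r <- rank(c(a, b))                 # midranks
    W <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    if (max(n1, n2) < 10L) {
        cmb <- utils::combn(N, n1)
        sums <- colSums(matrix(r[cmb], nrow = n1))
        p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-12)
    } else {
        tie <- table(r)
        tieCorr <- sum(tie^3 - tie)
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieCorr / (N * (N - 1)))
        if (sigma2 <= 0) {
            p <- 1
        } else {
            z <- W - mu
            z <- (z - sign(z) * 0.5) / sqrt(sigma2)
            p <- min(1, 2 * stats::pnorm(-abs(z)))
        }
    }
    list(statistic = W, p.value = p, reject = p < 0.05)
}

#' Friedman test with average ranks
#'
#' Ranks k methods within each of B blocks (midranks for ties; rank 1 is
#' best, where "best" follows `largerIsBetter`), reports the average
#' rank of each method, and tests the null of equal methods with the
#' tie-corrected chi-square approximation on k-1 degrees of freedom.
#'
#' @param blocks B x k numeric matrix of scores, one row per block and
#'   one column per method.
#' @param largerIsBetter if TRUE (default) larger scores rank better.
#' @return list with `averageRanks` (length k), `statistic`, `df`, and
#'   `p.value`.
#' @examples
#' m <- rbind(c(3, 2, 1), c(3, 1, 2), c(3, 2, 1), c(3, 2, 1))
#' friedmanRanks(m)$averageRanks  # method 1 always best: rank 1
#' @export
friedmanRanks <- function(blocks, largerIsBetter = TRUE) {
    blocks <- as.matrix(blocks)
    if (!is.numeric(blocks) || anyNA(blocks))
        stop("blocks must be a numeric matrix without NA")
    B <- nrow(blocks); k <- ncol(blocks)
    if (B < 2L || k < 2L)
        stop("need at least 2 blocks and 2 methods")
    R <- t(apply(blocks, 1L, function(x)
        rank(if (largerIsBetter) -x else x)))
    avg <- colMeans(R)
    names(avg) <- colnames(blocks)
    S <- sum((colSums(R) - B * (k + 1) / 2)^2)
    chi2 <- 12 * S / (B * k * (k + 1))
    tieSum <- sum(apply(blocks, 1L, function(x) {
        t <- table(x)
        sum(t^3 - t)
    }))
    C <- 1 - tieSum / (B * k * (k^2 - 1))
    if (C <= 0) {
        stat <- 0
        p <- 1
    } else {
        stat <- chi2 / C
        p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    }
    list(averageRanks = avg, statistic = stat, df = k - 1L, p.value = p)
}
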