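## Independent oracles, written straight from the defining formulas and
## kept free of the package's computational shortcuts (no prefix sums,
## no compiled code).

## Shannon-entropy sum over threshold classes, direct double loop.
naiveKapur <- function(hist, th) {
    p <- histProbs(hist)
    edges <- c(0L, as.integer(th), 256L)
    H <- 0
    for (i in seq_len(length(edges) - 1L)) {
        bins <- (edges[i]):(edges[i + 1L] - 1L)
        w <- sum(p[bins + 1L])
        if (w > 0) {
            for (j in bins) {
                pj <- p[j + 1L]
                if (pj > 0) H <- H - (pj / w) * log(pj / w)
            }
        }
    }
    H
}

## Between-class variance via the decomposition total = between + within.
naiveOtsuDecomp <- function(hist, th) {
    p <- histProbs(hist)
    lev <- 0:255
    muT <- sum(p * lev)
    totalVar <- sum(p * (lev - muT)^2)
    edges <- c(0L, as.integer(th), 256L)
    within <- 0
    for (i in seq_len(length(edges) - 1L)) {
        bins <- (edges[i]):(edges[i + 1L] - 1L)
        w <- sum(p[bins + 1L])
        if (w > 0) {
            mu <- sum(p[bins + 1L] * bins) / w
            within <- within + sum(p[bins + 1L] * (bins - mu)^2)
        }
    }
    totalVar - within
}

## Histogram with mass restricted to the first `support` gray levels.
seededHistogram <- function(seed, support = 16L, npix = 400L) {
    set.seed(seed)
    grayHistogram(matrix(sample.int(support, npix, replace = TRUE) - 1L,
                         nrow = 20L))
}

## Standalone whale-optimization loop (Algorithm-1 style, synchronous
## generations), with all move formulas written out inline. Mirrors the
## documented RNG schedule: per agent, donor index first, then the
## three uniforms for A, C, p, then the spiral draw if taken.
woaReference <- function(objective, K, nAgents, maxIter, seed,
                         b = 1, lower = 1, upper = 255) {
    set.seed(seed)
    pos <- matrix(runif(nAgents * K, lower, upper), nAgents, K)
    fit <- apply(pos, 1L, function(x) objective(decodeThresholds(x)))
    bestIdx <- which.max(fit)
    bestPos <- pos[bestIdx, ]
    bestFit <- fit[bestIdx]
    history <- numeric(maxIter)
    for (t in seq_len(maxIter)) {
        a <- 2 - 2 * t / maxIter
        old <- pos
        star <- bestPos
        for (i in seq_len(nAgents)) {
            j <- sample.int(nAgents, 1L)
            u <- runif(3)
            A <- 2 * a * u[1L] - a
            C <- 2 * u[2L]
            p <- u[3L]
            if (p >= 0.5) {
                l <- runif(1, -1, 1)
                x <- abs(star - old[i, ]) * exp(b * l) * cos(2 * pi * l) + star
            } else if (abs(A) < 1) {
                x <- star - A * abs(C * star - old[i, ])
            } else {
                x <- old[j, ] - A * abs(C * old[j, ] - old[i, ])
            }
            x <- pmin(pmax(x, lower), upper)
            pos[i, ] <- x
            fit[i] <- objective(decodeThresholds(x))
            if (fit[i] > bestFit) {
                bestFit <- fit[i]
                bestPos <- x
            }
        }
        history[t] <- bestFit
    }
    list(history = history, bestFit = bestFit,
         bestThresholds = decodeThresholds(bestPos))
}

## Exact two-sided rank-sum p-value by enumerating which observations
## land in the first sample (independent of the package's version).
enumRankSumP <- function(a, b) {
    n1 <- length(a)
    N <- n1 + length(b)
    r <- rank(c(a, b))
    obs <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    sets <- combn(N, n1)
    count <- 0L
    for (i in seq_len(ncol(sets)))
        if (abs(sum(r[sets[, i]]) - mu) >= abs(obs - mu) - 1e-12)
            count <- count + 1L
    count / ncol(sets)
}

## Friedman chi-square from the defining rank sums, with the standard
## tie correction factor.
friedmanFromDefinition <- function(mat, largerIsBetter = TRUE) {
    B <- nrow(mat); k <- ncol(mat)
    R <- matrix(0, B, k)
    for (i in seq_len(B))
        R[i, ] <- rank(if (largerIsBetter) -mat[i, ] else mat[i, ])
    chi2 <- 12 / (B * k * (k + 1)) * sum((colSums(R) - B * (k + 1) / 2)^2)
    ties <- 0
    for (i in seq_len(B)) {
        tt <- table(mat[i, ])
        ties <- ties + sum(tt^3 - tt)
    }
    C <- 1 - ties / (B * k * (k^2 - 1))
    if (C <= 0) return(list(statistic = 0, p.value = 1))
    stat <- chi2 / C
    list(statistic = stat,
         p.value = pchisq(stat, k - 1, lower.tail = FALSE))
}
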