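test_that("the exploration coefficient decays linearly from 2 to 0", {
    expect_equal(aSchedule(0, 500), 2)
    expect_equal(aSchedule(500, 500), 0)
    expect_equal(aSchedule(250, 500), 1)
    ## |A| <= a, so A is confined to [-1,1] exactly from the iteration
    ## where a first reaches 1: halfway through the run
    a <- vapply(0:500, aSchedule, numeric(1), maxIter = 500)
    expect_equal((0:500)[which(a <= 1)[1]], 250)
    expect_error(aSchedule(-1, 500), "\\[0, maxIter\\]")
    expect_error(aSchedule(501, 500), "\\[0, maxIter\\]")
})

test_that("whale moves reproduce the three update formulas", {
    ## replay the RNG stream and hand-evaluate each branch in 1-D
    branches <- c(spiral = 0L, encircle = 0L, explore = 0L)
    for (s in 1:40) {
        for (a in c(0.4, 1.8)) {
            x <- 30; xs <- 120; xr <- 200; b <- 1
            set.seed(s)
            u <- runif(3)
            A <- 2 * a * u[1] - a
            C <- 2 * u[2]
            p <- u[3]
            if (p >= 0.5) {
                l <- runif(1, -1, 1)
                expected <- abs(xs - x) * exp(b * l) * cos(2 * pi * l) + xs
                branches["spiral"] <- branches["spiral"] + 1L
            } else if (abs(A) < 1) {
                expected <- xs - A * abs(C * xs - x)
                branches["encircle"] <- branches["encircle"] + 1L
            } else {
                expected <- xr - A * abs(C * xr - x)
                branches["explore"] <- branches["explore"] + 1L
            }
            expected <- min(max(expected, 1), 255)
            set.seed(s)
            expect_equal(woaMove(x, xs, xr, a), expected, tolerance = 1e-12)
        }
    }
    expect_true(all(branches > 0L))   # every branch exercised

    ## spiral update is a fixed point when the agent sits on the best
    set.seed(5)   # seed whose p lands >= 0.5
    u <- runif(3)
    stopifnot(u[3] >= 0.5)
    set.seed(5)
    expect_equal(woaMove(c(50, 80), c(50, 80), c(10, 10), a = 1),
                 c(50, 80))

    expect_error(woaMove(1:2, 1:3, 1:2, 1), "dimension")
    expect_error(woaMove(1, 1, 1, a = 3), "\\[0, 2\\]")
})

test_that("differential-evolution operators follow their contracts", {
    expect_equal(deMutation(c(5, 9), c(7, 7), c(7, 7), SF = 0.5), c(5, 9))
    expect_equal(deMutation(10, 20, 12, SF = 0.5), 14)
    expect_equal(deMutation(250, 255, 1, SF = 0.5), 255)   # clamped from 377

    x <- c(1, 2, 3, 4); m <- c(10, 20, 30, 40)
    expect_equal(deCrossover(x, m, CR = 1), m)
    expect_equal(deCrossover(x, m, CR = 0), x)
    set.seed(11)
    trial <- deCrossover(x, m, CR = 0.9)
    set.seed(11)
    expect_equal(trial, ifelse(runif(4) <= 0.9, m, x))
    expect_error(deCrossover(1:2, 1:3, 0.5), "dimension")

    f <- function(pos) -sum((pos - 3)^2)
    expect_equal(deSelection(c(0, 0), c(3, 3), f), c(3, 3))
    expect_equal(deSelection(c(3, 3), c(3, 3), f), c(3, 3))  # tie keeps x
    g <- function(pos) 7                                     # constant
    expect_equal(deSelection(c(1, 2), c(200, 4), g), c(1, 2))
})

test_that("decoded positions always form valid threshold vectors", {
    for (s in 1:50) {
        set.seed(s)
        K <- sample(1:12, 1)
        pos <- runif(K, 1, 255)
        th <- decodeThresholds(pos)
        expect_length(th, K)
        expect_true(all(th >= 1 & th <= 255))
        if (K > 1) expect_true(all(diff(th) >= 1))
    }
    ## duplicate repair spills downward at the top of the range
    expect_equal(decodeThresholds(c(255, 255, 255)), c(253L, 254L, 255L))
    expect_equal(decodeThresholds(c(10.4, 9.6, 10.2)), c(10L, 11L, 12L))
})

test_that("the optimizer solves a landscape with a known global optimum", {
    uni4 <- grayHistogram(matrix(c(0, 1, 2, 3), 2, 2))
    obj <- function(th) kapurEntropy(uni4, th)
    ## the optimum value 2 ln 2 is attained at th = 2 (balanced split)
    ## and, with the empty-class convention, by any th >= 4 (all mass in
    ## one class of entropy ln 4); the value is what the oracle certifies
    bf <- bruteForceOptimum(uni4, 1, "kapur")
    expect_equal(bf$thresholds, 2L)
    expect_equal(bf$fitness, 2 * log(2), tolerance = 1e-12)
    for (s in c(1, 2, 3)) {
        res <- optimizeThresholds(obj, 1,
            optimizerConfig(nAgents = 30, maxIter = 50, seed = s))
        expect_equal(bestFitness(res), 2 * log(2), tolerance = 1e-12)
        expect_equal(kapurEntropy(uni4, bestThresholds(res)),
                     bestFitness(res), tolerance = 1e-12)
    }
})

test_that("a constant objective leaves the population and history flat", {
    res <- optimizeThresholds(function(th) 3.5, 2,
        optimizerConfig(nAgents = 8, maxIter = 20, seed = 9))
    expect_equal(convergence(res), rep(3.5, 20))
    expect_equal(bestFitness(res), 3.5)
    ## equal fitness means no agent is above the mean: WOA branch only
    expect_equal(res@deMoves, 0L)
    expect_equal(res@woaMoves, 8L * 20L)
})

test_that("convergence history is non-decreasing for every algorithm", {
    h <- seededHistogram(31, support = 200L)
    obj <- function(th) kapurEntropy(h, th)
    for (alg in c("woa_de", "woa", "de")) {
        for (s in 1:3) {
            res <- optimizeThresholds(obj, 3,
                optimizerConfig(nAgents = 10, maxIter = 40, seed = s), alg)
            expect_true(all(diff(convergence(res)) >= 0))
            expect_equal(bestFitness(res),
                         convergence(res)[length(convergence(res))])
            expect_true(all(bestThresholds(res) >= 1 &
                            bestThresholds(res) <= 255))
        }
    }
})

test_that("the pure-WOA path reproduces a standalone whale loop", {
    h <- seededHistogram(53, support = 100L)
    obj <- function(th) kapurEntropy(h, th)
    for (s in c(2, 8)) {
        ref <- woaReference(obj, K = 1, nAgents = 8, maxIter = 30, seed = s)
        res <- optimizeThresholds(obj, 1,
            optimizerConfig(nAgents = 8, maxIter = 30, seed = s), "woa")
        expect_equal(convergence(res), ref$history, tolerance = 1e-12)
        expect_equal(bestThresholds(res), ref$bestThresholds)
    }
})

test_that("configuration invariants are enforced", {
    expect_error(optimizerConfig(nAgents = 3), ">= 4")
    expect_error(optimizerConfig(CR = 1.2), "\\[0, 1\\]")
    expect_error(optimizerConfig(SF = 0), "positive")
    expect_error(optimizeThresholds(function(th) 1, 0), "positive integer")
})

test_that("optimizer runs are reproducible and leave the caller's RNG alone", {
    h <- seededHistogram(77)
    obj <- function(th) kapurEntropy(h, th)
    cfg <- optimizerConfig(nAgents = 6, maxIter = 10, seed = 5)
    set.seed(1); before <- runif(1)
    set.seed(1)
    r1 <- optimizeThresholds(obj, 2, cfg)
    after <- runif(1)
    r2 <- optimizeThresholds(obj, 2, cfg)
    expect_equal(convergence(r1), convergence(r2))
    expect_equal(bestThresholds(r1), bestThresholds(r2))
    expect_identical(before, after)
})
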