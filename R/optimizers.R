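#' Construct an optimizer configuration
#'
#' Defaults follow common practice for threshold metaheuristics:
#' population of 30 agents, 500 iterations, DE crossover rate CR = 0.9,
#' mutation scaling factor SF = 0.5, logarithmic-spiral constant b = 1,
#' and search bounds \[1, 255\] (the admissible threshold gray levels).
#'
#' @param nAgents population size (>= 4).
#' @param maxIter iteration budget.
#' @param CR crossover probability in \[0, 1\].
#' @param SF mutation scaling factor (> 0).
#' @param b spiral shape constant.
#' @param seed integer seed for the run's single RNG stream, or NA to
#'   use the current RNG state.
#' @param lower,upper continuous search bounds.
#' @return an [OptimizerConfig-class] object.
#' @export
optimizerConfig <- function(nAgents = 30, maxIter = 500, CR = 0.9, SF = 0.5,
                            b = 1, seed = NA, lower = 1, upper = 255) {
    new("OptimizerConfig",
        nAgents = as.integer(nAgents), maxIter = as.integer(maxIter),
        CR = as.numeric(CR), SF = as.numeric(SF), b = as.numeric(b),
        seed = as.integer(seed), lower = as.numeric(lower),
        upper = as.numeric(upper))
}

## Run code() under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    if (is.null(seed) || is.na(seed))
        return(code())
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    code()
}

#' Linearly decaying exploration coefficient
#'
#' The control parameter a decreases linearly from 2 at the start of the
#' run to 0 at the last iteration: a(t) = 2 - 2 t / maxIter. The step
#' coefficient A = 2 a r - a (r uniform on \[0, 1\]) then satisfies
#' |A| <= a, so from iteration maxIter/2 onward A is confined to
#' \[-1, 1\] and the whale moves are purely exploitative.
#'
#' @param t iteration index, 0..maxIter.
#' @param maxIter iteration budget.
#' @return the coefficient a in \[0, 2\].
#' @examples
#' aSchedule(0, 500)    # 2
#' aSchedule(250, 500)  # 1: |A| <= 1 from here on
#' @export
aSchedule <- function(t, maxIter) {
    if (!is.numeric(t) || length(t) != 1L || t < 0 || t > maxIter)
        stop("t must lie in [0, maxIter]")
    2 - 2 * t / maxIter
}

#' Decode a continuous agent position into a valid threshold vector
#'
#' Coordinates are sorted, rounded to the nearest integer and clamped to
#' \[1, 255\]; duplicate values are repaired by incrementing collided
#' values upward, spilling downward when the top of the range is hit.
#' The result always satisfies the strict-increase invariant.
#'
#' @param position numeric vector of K coordinates.
#' @return integer vector of K strictly increasing thresholds in
#'   \[1, 255\].
#' @export
decodeThresholds <- function(position) {
    K <- length(position)
    if (K == 0L) stop("position is empty")
    if (K > 255L) stop("more thresholds than distinct gray levels")
    v <- as.integer(pmin(pmax(round(sort(position)), 1), 255))
    if (K > 1L) {
        for (i in 2:K)
            if (v[i] <= v[i - 1L]) v[i] <- v[i - 1L] + 1L
        if (v[K] > 255L) {
            v[K] <- 255L
            for (i in (K - 1L):1L)
                if (v[i] >= v[i + 1L]) v[i] <- v[i + 1L] - 1L
        }
    }
    v
}

#' One whale-optimization position update
#'
#' Draws the stochastic controls for one agent — rA and rC uniform on
#' \[0, 1\] giving A = 2 a rA - a and C = 2 rC, then the branch
#' selector p uniform on \[0, 1\] — and applies one of the three whale
#' moves:
#' \itemize{
#'   \item p >= 0.5: logarithmic-spiral (bubble-net) update
#'     x' = D' e^{b l} cos(2 pi l) + x*, with D' = |x* - x| elementwise
#'     and l uniform on \[-1, 1\];
#'   \item p < 0.5 and |A| < 1: encircling update x' = x* - A |C x* - x|
#'     (exploitation around the best solution so far);
#'   \item p < 0.5 and |A| >= 1: search-for-prey update
#'     x' = x_rand - A |C x_rand - x| (exploration around a random
#'     agent).
#' }
#' The result is clamped to the search bounds.
#'
#' @param x current position.
#' @param xStar best position found so far.
#' @param xRand position of a randomly chosen agent (used only by the
#'   exploration branch, but always required so the caller's RNG
#'   schedule is branch-independent).
#' @param a decay coefficient from [aSchedule()].
#' @param b spiral shape constant.
#' @param lower,upper clamp bounds.
#' @return the updated position (numeric vector, same length as `x`).
#' @export
woaMove <- function(x, xStar, xRand, a, b = 1, lower = 1, upper = 255) {
    d <- length(x)
    if (length(xStar) != d || length(xRand) != d)
        stop("position dimension mismatch")
    if (a < 0 || a > 2)
        stop("a must lie in [0, 2]")
    u <- stats::runif(3)
    A <- 2 * a * u[1L] - a
    C <- 2 * u[2L]
    p <- u[3L]
    if (p >= 0.5) {
        l <- stats::runif(1, -1, 1)
        Dp <- abs(xStar - x)
        xnew <- Dp * exp(b * l) * cos(2 * pi * l) + xStar
    } else if (abs(A) < 1) {
        D <- abs(C * xStar - x)
        xnew <- xStar - A * D
    } else {
        D <- abs(C * xRand - x)
        xnew <- xRand - A * D
    }
    pmin(pmax(xnew, lower), upper)
}

#' Differential-evolution mutation (rand/1)
#'
#' m = x_r1 + SF (x_r2 - x_r3), clamped to the bounds. The three donor
#' agents must be pairwise distinct population members.
#'
#' @param xr1,xr2,xr3 donor positions.
#' @param SF scaling factor.
#' @param lower,upper clamp bounds.
#' @return the mutant position.
#' @export
deMutation <- function(xr1, xr2, xr3, SF, lower = 1, upper = 255) {
    if (length(xr2) != length(xr1) || length(xr3) != length(xr1))
        stop("position dimension mismatch")
    pmin(pmax(xr1 + SF * (xr2 - xr3), lower), upper)
}

#' Differential-evolution binomial crossover
#'
#' Per coordinate, the trial takes the mutant value when a fresh uniform
#' draw is <= CR and the current value otherwise.
#'
#' @param x current position.
#' @param m mutant position.
#' @param CR crossover probability.
#' @return the trial position.
#' @export
deCrossover <- function(x, m, CR) {
    if (length(m) != length(x))
        stop("position dimension mismatch")
    take <- stats::runif(length(x)) <= CR
    ifelse(take, m, x)
}

#' Differential-evolution greedy selection (maximization)
#'
#' Keeps the trial only if it strictly improves the objective; ties keep
#' the incumbent. The objective here is maximized (entropy / variance),
#' so the textbook minimization rule is mirrored.
#'
#' @param x incumbent position.
#' @param trial trial position.
#' @param f objective: a function of a position returning a numeric
#'   fitness.
#' @return the surviving position.
#' @export
deSelection <- function(x, trial, f) {
    if (f(trial) > f(x)) trial else x
}

#' Search for optimal thresholds with WOA-DE, WOA or DE
#'
#' Runs a population of agents over continuous positions in
#' \[lower, upper\]^K; every evaluation decodes a position to a valid
#' integer threshold vector (see [decodeThresholds()]) and scores it
#' with the supplied objective, which is maximized.
#'
#' The hybrid rule ("woa_de") splits each generation by the mean
#' population fitness f-bar: agents with fitness above f-bar take a
#' differential-evolution step (rand/1 mutation, binomial crossover,
#' greedy selection) to exploit their promising neighborhood; agents at
#' or below f-bar take a whale-optimization step (encircling, spiral or
#' random search depending on the decaying coefficient a) to keep
#' exploring. "woa" and "de" run the pure algorithms at the same
#' budget. Generations are synchronous: f-bar, the best-so-far attractor
#' and the donor pool are all taken from the population state at the top
#' of the iteration, so results are independent of agent order.
#'
#' @param objective function taking an integer threshold vector and
#'   returning a numeric fitness (e.g. built from [kapurEntropy()]).
#' @param K number of thresholds (problem dimension).
#' @param config an [OptimizerConfig-class]; its seed fixes the run.
#' @param algorithm "woa_de" (default), "woa" or "de".
#' @return an [OptimizerResult-class].
#' @examples
#' h <- grayHistogram(matrix(c(0, 1, 2, 3), 2, 2))
#' obj <- function(th) kapurEntropy(h, th)
#' res <- optimizeThresholds(obj, K = 1,
#'     optimizerConfig(nAgents = 10, maxIter = 25, seed = 1))
#' bestThresholds(res)
#' @export
optimizeThresholds <- function(objective, K,
                               config = optimizerConfig(),
                               algorithm = c("woa_de", "woa", "de")) {
    algorithm <- match.arg(algorithm)
    stopifnot(is(config, "OptimizerConfig"))
    validObject(config)
    if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 1L)
        stop("K must be a positive integer")
    n <- config@nAgents
    maxIter <- config@maxIter
    .withSeed(config@seed, function() {
        pos <- matrix(stats::runif(n * K, config@lower, config@upper),
                      nrow = n, ncol = K)
        fit <- numeric(n)
        evals <- 0L
        for (i in seq_len(n)) {
            fit[i] <- objective(decodeThresholds(pos[i, ]))
            evals <- evals + 1L
        }
        ib <- which.max(fit)
        bestPos <- pos[ib, ]
        bestFit <- fit[ib]
        history <- numeric(maxIter)
        woaMoves <- 0L
        deMoves <- 0L
        for (t in seq_len(maxIter)) {
            a <- aSchedule(t, maxIter)
            fbar <- mean(fit)
            oldPos <- pos
            oldFit <- fit
            starPos <- bestPos   # attractor frozen for the whole generation
            for (i in seq_len(n)) {
                useDE <- switch(algorithm,
                    woa_de = oldFit[i] > fbar,
                    woa = FALSE,
                    de = TRUE)
                if (useDE) {
                    others <- seq_len(n)[-i]
                    r <- others[sample.int(n - 1L, 3L)]
                    m <- deMutation(oldPos[r[1L], ], oldPos[r[2L], ],
                                    oldPos[r[3L], ], config@SF,
                                    config@lower, config@upper)
                    trial <- deCrossover(oldPos[i, ], m, config@CR)
                    fTrial <- objective(decodeThresholds(trial))
                    evals <- evals + 1L
                    if (fTrial > oldFit[i]) {
                        pos[i, ] <- trial
                        fit[i] <- fTrial
                    } else {
                        pos[i, ] <- oldPos[i, ]
                        fit[i] <- oldFit[i]
                    }
                    deMoves <- deMoves + 1L
                } else {
                    j <- sample.int(n, 1L)
                    xnew <- woaMove(oldPos[i, ], starPos, oldPos[j, ], a,
                                    config@b, config@lower, config@upper)
                    fNew <- objective(decodeThresholds(xnew))
                    evals <- evals + 1L
                    pos[i, ] <- xnew
                    fit[i] <- fNew
                    woaMoves <- woaMoves + 1L
                }
                if (fit[i] > bestFit) {
                    bestFit <- fit[i]
                    bestPos <- pos[i, ]
                }
            }
            history[t] <- bestFit
        }
        new("OptimizerResult",
            bestThresholds = decodeThresholds(bestPos),
            bestFitness = bestFit,
            history = history,
            evaluations = evals,
            algorithm = algorithm,
            woaMoves = woaMoves,
            deMoves = deMoves)
    })
}
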