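#' Repeated-run thresholding experiment
#'
#' Executes the full evaluation protocol: for every combination of
#' image, threshold count K, objective and algorithm, runs `nRuns`
#' independently seeded searches (run seeds are baseSeed + run index -
#' 1, channel seeds derived inside the segmentation step), records the
#' best fitness and the PSNR/SSIM/FSIM of the reconstructed image, and
#' aggregates mean fitness with its sample standard deviation. The
#' whole experiment is a deterministic function of (spec, baseSeed).
#'
#' @param images named list of image arrays (integers in \[0, 255\]) or
#'   file paths readable by [readImageArray()].
#' @param KLevels integer vector of threshold counts.
#' @param objectives character subset of c("kapur", "otsu").
#' @param algorithms character subset of c("woa_de", "woa", "de").
#' @param nRuns runs per cell (30 in the full protocol).
#' @param baseSeed integer; run r of every cell uses baseSeed + r - 1.
#' @param nAgents,maxIter optimizer budget per run.
#' @param computeMetrics if FALSE, skip PSNR/SSIM/FSIM (faster; fitness
#'   columns only).
#' @param outputDir if non-NULL, write `runs.csv`, `summary.csv` and
#'   `convergence.csv` there.
#' @return list with data frames `runs` (one row per run) and `summary`
#'   (one row per cell), plus `convergence` (iteration-by-iteration
#'   best fitness per cell, first run).
#' @export
runExperiment <- function(images, KLevels, objectives = "kapur",
                          algorithms = "woa_de", nRuns = 30,
                          baseSeed = 1, nAgents = 30, maxIter = 500,
                          computeMetrics = TRUE, outputDir = NULL) {
    if (length(KLevels) == 0L) stop("KLevels must be nonempty")
    if (nRuns < 1L) stop("nRuns must be >= 1")
    objectives <- match.arg(objectives, c("kapur", "otsu"), several.ok = TRUE)
    algorithms <- match.arg(algorithms, c("woa_de", "woa", "de"),
                            several.ok = TRUE)
    if (is.null(names(images)))
        names(images) <- paste0("image", seq_along(images))
    images <- lapply(images, function(im) {
        if (is.character(im)) {
            if (!file.exists(im))
                stop("unreadable image: ", im)
            im <- readImageArray(im)
        }
        .validateImageArray(im)
        im
    })

    runs <- list()
    conv <- list()
    for (imName in names(images)) {
        img <- images[[imName]]
        for (K in KLevels) {
            for (obj in objectives) {
                for (alg in algorithms) {
                    for (r in seq_len(nRuns)) {
                        seed <- baseSeed + r - 1L
                        cfg <- optimizerConfig(nAgents = nAgents,
                                               maxIter = maxIter,
                                               seed = seed)
                        res <- tryCatch(
                            thresholdImage(img, K, obj, cfg, alg),
                            error = function(e) stop(
                                "cell (", imName, ", K=", K, ", ", obj,
                                ", ", alg, ", run ", r, ") failed: ",
                                conditionMessage(e)))
                        row <- data.frame(
                            image = imName, K = K, objective = obj,
                            algorithm = alg, run = r, seed = seed,
                            fitness = totalFitness(res),
                            stringsAsFactors = FALSE)
                        if (computeMetrics) {
                            seg <- segmentedImage(res)
                            row$psnr <- msePsnr(img, seg)$psnr
                            row$ssim <- imageSSIM(img, seg)
                            row$fsim <- imageFSIM(img, seg)
                        }
                        runs[[length(runs) + 1L]] <- row
                        if (r == 1L) {
                            ## per-cell convergence curve from a direct
                            ## single-channel run on the first channel
                            h <- grayHistogram(.getChannel(img, 1L))
                            f <- .objectiveFun(obj)
                            or <- optimizeThresholds(
                                function(th) f(h, th), K, cfg, alg)
                            conv[[length(conv) + 1L]] <- data.frame(
                                image = imName, K = K, objective = obj,
                                algorithm = alg,
                                iteration = seq_along(convergence(or)),
                                best_fitness = convergence(or),
                                stringsAsFactors = FALSE)
                        }
                    }
                }
            }
        }
    }
    runs <- do.call(rbind, runs)
    conv <- do.call(rbind, conv)

    cellKey <- interaction(runs$image, runs$K, runs$objective,
                           runs$algorithm, drop = TRUE)
    summary <- do.call(rbind, lapply(split(runs, cellKey), function(d) {
        out <- data.frame(
            image = d$image[1L], K = d$K[1L], objective = d$objective[1L],
            algorithm = d$algorithm[1L], n_runs = nrow(d),
            mean_fitness = mean(d$fitness),
            std_fitness = if (nrow(d) >= 2L) fitnessStd(d$fitness) else 0,
            stringsAsFactors = FALSE)
        if (computeMetrics) {
            out$mean_psnr <- mean(d$psnr)
            out$mean_ssim <- mean(d$ssim)
            out$mean_fsim <- mean(d$fsim)
        }
        out
    }))
    rownames(summary) <- NULL
    summary <- summary[order(summary$image, summary$K, summary$objective,
                             summary$algorithm), , drop = FALSE]
    rownames(summary) <- NULL

    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(runs, file.path(outputDir, "runs.csv"),
                         row.names = FALSE)
        utils::write.csv(summary, file.path(outputDir, "summary.csv"),
                         row.names = FALSE)
        utils::write.csv(conv, file.path(outputDir, "convergence.csv"),
                         row.names = FALSE)
    }
    list(runs = runs, summary = summary, convergence = conv)
}

#' Nonparametric comparisons on an experiment's run table
#'
#' `test = "ranksum"` compares the first algorithm in `runs` against
#' every other algorithm within each (image, K, objective) cell with
#' the two-sided Wilcoxon rank-sum test on the chosen per-run measure.
#' `test = "friedman"` ranks the algorithms within each (image,
#' objective, run) block separately for every K and reports average
#' ranks and the tie-corrected p-value.
#'
#' @param runs the `runs` data frame from [runExperiment()].
#' @param measure column to compare ("fitness", "psnr", "ssim", "fsim").
#' @param test "ranksum" or "friedman".
#' @param largerIsBetter rank direction for the Friedman test.
#' @return a data frame of test results.
#' @export
experimentStats <- function(runs, measure = "fitness",
                            test = c("ranksum", "friedman"),
                            largerIsBetter = TRUE) {
    test <- match.arg(test)
    if (!measure %in% names(runs))
        stop("measure '", measure, "' not found in runs")
    algs <- unique(runs$algorithm)
    if (test == "ranksum") {
        if (length(algs) < 2L)
            stop("rank-sum comparison needs at least two algorithms")
        ref <- algs[1L]
        cells <- unique(runs[, c("image", "K", "objective")])
        out <- list()
        for (i in seq_len(nrow(cells))) {
            sel <- runs$image == cells$image[i] & runs$K == cells$K[i] &
                runs$objective == cells$objective[i]
            a <- runs[sel & runs$algorithm == ref, measure]
            for (other in algs[-1L]) {
                b <- runs[sel & runs$algorithm == other, measure]
                rs <- rankSumTest(a, b)
                out[[length(out) + 1L]] <- data.frame(
                    image = cells$image[i], K = cells$K[i],
                    objective = cells$objective[i],
                    comparison = paste(ref, "vs", other),
                    p_value = rs$p.value, h = as.integer(rs$reject),
                    stringsAsFactors = FALSE)
            }
        }
        return(do.call(rbind, out))
    }
    if (length(algs) < 2L)
        stop("Friedman test needs at least two algorithms")
    out <- list()
    for (K in sort(unique(runs$K))) {
        d <- runs[runs$K == K, , drop = FALSE]
        block <- interaction(d$image, d$objective, d$run, drop = TRUE)
        mat <- matrix(NA_real_, nlevels(block), length(algs),
                      dimnames = list(NULL, algs))
        for (j in seq_along(algs)) {
            dj <- d[d$algorithm == algs[j], , drop = FALSE]
            bj <- interaction(dj$image, dj$objective, dj$run, drop = FALSE)
            mat[match(as.character(bj), levels(block)), j] <- dj[[measure]]
        }
        if (anyNA(mat))
            stop("unbalanced design: every algorithm needs every block")
        fr <- friedmanRanks(mat, largerIsBetter = largerIsBetter)
        out[[length(out) + 1L]] <- data.frame(
            K = K, algorithm = algs, average_rank = unname(fr$averageRanks),
            p_value = fr$p.value, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
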