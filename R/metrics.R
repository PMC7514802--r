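## ---- convolution helpers ---------------------------------------------------

## 2-D correlation keeping only the fully-overlapped ("valid") region
.filter2valid <- function(x, w) {
    kr <- nrow(w); kc <- ncol(w)
    nr <- nrow(x) - kr + 1L; nc <- ncol(x) - kc + 1L
    if (nr < 1L || nc < 1L)
        stop("image smaller than the filter support")
    out <- matrix(0, nr, nc)
    for (i in seq_len(kr))
        for (j in seq_len(kc))
            out <- out + w[i, j] * x[i:(i + nr - 1L), j:(j + nc - 1L)]
    out
}

## 2-D correlation with zero padding, output same size as input
.filter2same <- function(x, w) {
    kr <- nrow(w); kc <- ncol(w)
    pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
    xp <- matrix(0, nrow(x) + kr - 1L, ncol(x) + kc - 1L)
    xp[(pr + 1L):(pr + nrow(x)), (pc + 1L):(pc + ncol(x))] <- x
    .filter2valid(xp, w)
}

.gaussianKernel <- function(size = 11L, sigma = 1.5) {
    half <- (size - 1L) / 2
    g <- exp(-((-half):half)^2 / (2 * sigma^2))
    k <- outer(g, g)
    k / sum(k)
}

.checkSameShape <- function(a, b) {
    if (!identical(dim(a), dim(b)))
        stop("images must have the same shape")
}

.luminance <- function(image) {
    if (length(dim(image)) == 3L)
        0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
    else
        image
}

## ---- MSE / PSNR ------------------------------------------------------------

#' Mean squared error and peak signal-to-noise ratio
#'
#' MSE is averaged over all pixels (and channels for RGB); PSNR is
#' 10 log10(255^2 / MSE) in dB, with +Inf for identical images.
#'
#' @param original,segmented images of identical shape on the 0..255
#'   scale.
#' @return list with elements `mse` and `psnr`.
#' @examples
#' a <- matrix(0, 2, 2); b <- a; b[1, 1] <- 1
#' msePsnr(a, b)$psnr  # ~54.15 dB
#' @export
msePsnr <- function(original, segmented) {
    .checkSameShape(original, segmented)
    mse <- mean((as.numeric(original) - as.numeric(segmented))^2)
    psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
    list(mse = mse, psnr = psnr)
}

## ---- SSIM ------------------------------------------------------------------

.ssimChannel <- function(x, y, method, C1, C2) {
    if (method == "global") {
        mx <- mean(x); my <- mean(y)
        vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
        cxy <- mean(x * y) - mx * my
        return(((2 * mx * my + C1) * (2 * cxy + C2)) /
               ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
    w <- .gaussianKernel(11L, 1.5)
    mx <- .filter2valid(x, w); my <- .filter2valid(y, w)
    vx <- .filter2valid(x^2, w) - mx^2
    vy <- .filter2valid(y^2, w) - my^2
    cxy <- .filter2valid(x * y, w) - mx * my
    num <- (2 * mx * my + C1) * (2 * cxy + C2)
    den <- (mx^2 + my^2 + C1) * (vx + vy + C2)
    mean(num / den)
}

#' Structural similarity index
#'
#' Computed on the 0..255 scale with the standard regularizers
#' c1 = (0.01 * 255)^2 and c2 = (0.03 * 255)^2. The default "windowed"
#' method uses local 11x11 Gaussian-weighted statistics (sigma 1.5)
#' averaged over the image; the "global" method evaluates the formula
#' once with whole-image moments. RGB images are scored per channel and
#' averaged.
#'
#' @inheritParams msePsnr
#' @param method "windowed" (default) or "global".
#' @return similarity in \[-1, 1\], 1 for identical images.
#' @export
imageSSIM <- function(original, segmented, method = c("windowed", "global")) {
    method <- match.arg(method)
    .checkSameShape(original, segmented)
    C1 <- (0.01 * 255)^2
    C2 <- (0.03 * 255)^2
    nch <- .nChannels(original)
    vals <- vapply(seq_len(nch), function(ch)
        .ssimChannel(.getChannel(original, ch), .getChannel(segmented, ch),
                     method, C1, C2),
        numeric(1))
    mean(vals)
}

## ---- FSIM ------------------------------------------------------------------

.ifftshiftIdx <- function(n) c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))

.ifftshift2 <- function(m) {
    m[.ifftshiftIdx(nrow(m)), .ifftshiftIdx(ncol(m))]
}

## Phase congruency map from a log-Gabor filter bank (4 scales x 4
## orientations, minimum wavelength 6, scale multiplier 2, radial
## bandwidth sigmaOnf 0.55, noise threshold k = 2 standard deviations).
.phaseCongruency <- function(im, nscale = 4L, norient = 4L,
                             minWaveLength = 6, mult = 2, sigmaOnf = 0.55,
                             k = 2, epsilon = 1e-4) {
    rows <- nrow(im); cols <- ncol(im)
    IM <- stats::fft(im)

    rng <- function(n) {
        if (n %% 2L == 0L) (-(n / 2):(n / 2 - 1)) / n
        else ((-(n - 1) / 2):((n - 1) / 2)) / (n - 1)
    }
    x <- matrix(rng(cols), rows, cols, byrow = TRUE)
    y <- matrix(rng(rows), rows, cols)
    radius <- .ifftshift2(sqrt(x^2 + y^2))
    theta <- .ifftshift2(atan2(-y, x))
    radius[1L, 1L] <- 1
    sintheta <- sin(theta); costheta <- cos(theta)

    lp <- 1 / (1 + (radius / 0.45)^(2 * 15))   # lowpass to kill FFT wraparound
    logGabor <- vector("list", nscale)
    for (s in seq_len(nscale)) {
        wavelength <- minWaveLength * mult^(s - 1)
        fo <- 1 / wavelength
        g <- exp(-(log(radius / fo))^2 / (2 * log(sigmaOnf)^2)) * lp
        g[1L, 1L] <- 0
        logGabor[[s]] <- g
    }

    thetaSigma <- pi / norient / 1.2
    EnergyAll <- matrix(0, rows, cols)
    AnAll <- matrix(0, rows, cols)
    npts <- rows * cols

    for (o in seq_len(norient)) {
        angl <- (o - 1) * pi / norient
        ds <- sintheta * cos(angl) - costheta * sin(angl)
        dc <- costheta * cos(angl) + sintheta * sin(angl)
        dtheta <- abs(atan2(ds, dc))
        spread <- exp(-dtheta^2 / (2 * thetaSigma^2))

        sumE <- matrix(0, rows, cols)
        sumO <- matrix(0, rows, cols)
        sumAn <- matrix(0, rows, cols)
        Es <- vector("list", nscale)
        Os <- vector("list", nscale)
        tau <- 0
        for (s in seq_len(nscale)) {
            filt <- logGabor[[s]] * spread
            EO <- stats::fft(IM * filt, inverse = TRUE) / npts
            Es[[s]] <- Re(EO)
            Os[[s]] <- Im(EO)
            An <- Mod(EO)
            sumAn <- sumAn + An
            sumE <- sumE + Es[[s]]
            sumO <- sumO + Os[[s]]
            if (s == 1L)
                tau <- stats::median(An) / sqrt(log(4))
        }
        XEnergy <- sqrt(sumE^2 + sumO^2) + epsilon
        MeanE <- sumE / XEnergy
        MeanO <- sumO / XEnergy
        Energy <- matrix(0, rows, cols)
        for (s in seq_len(nscale)) {
            Energy <- Energy + Es[[s]] * MeanE + Os[[s]] * MeanO -
                abs(Es[[s]] * MeanO - Os[[s]] * MeanE)
        }
        ## expected noise response, estimated from the smallest scale
        totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
        noiseMean <- totalTau * sqrt(pi / 2)
        noiseSigma <- totalTau * sqrt((4 - pi) / 2)
        Energy <- pmax(Energy - (noiseMean + k * noiseSigma), 0)
        EnergyAll <- EnergyAll + Energy
        AnAll <- AnAll + sumAn
    }
    EnergyAll / (AnAll + epsilon)
}

.scharrX <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3L, 3L) / 16
.scharrY <- t(.scharrX)

.gradientMagnitude <- function(im) {
    gx <- .filter2same(im, .scharrX)
    gy <- .filter2same(im, .scharrY)
    sqrt(gx^2 + gy^2)
}

## internal: the maps FSIM combines, exposed for from-formula re-evaluation
.fsimComponents <- function(original, segmented) {
    .checkSameShape(original, segmented)
    y1 <- .luminance(original)
    y2 <- .luminance(segmented)
    if (min(dim(y1)) < 16L)
        stop("image smaller than the log-Gabor filter bank support")
    list(pc1 = .phaseCongruency(y1), pc2 = .phaseCongruency(y2),
         g1 = .gradientMagnitude(y1), g2 = .gradientMagnitude(y2))
}

#' Feature similarity index
#'
#' Combines a phase-congruency similarity and a gradient-magnitude
#' similarity at every pixel,
#' \deqn{S_L = S_{PC} \cdot S_G,\quad
#'       S_{PC} = \frac{2 PC_1 PC_2 + T_1}{PC_1^2 + PC_2^2 + T_1},\quad
#'       S_G = \frac{2 G_1 G_2 + T_2}{G_1^2 + G_2^2 + T_2},}
#' and averages S_L weighted by the pointwise maximum phase congruency
#' PC_m = max(PC_1, PC_2). Phase congruency comes from a log-Gabor bank
#' (4 scales x 4 orientations), gradients from Scharr operators;
#' T1 = 0.85, T2 = 160 on the 0..255 scale. RGB images are scored on
#' the luminance channel (0.299 R + 0.587 G + 0.114 B).
#'
#' @inheritParams msePsnr
#' @return similarity in (0, 1\], 1 for identical images.
#' @export
imageFSIM <- function(original, segmented) {
    comp <- .fsimComponents(original, segmented)
    T1 <- 0.85; T2 <- 160
    spc <- (2 * comp$pc1 * comp$pc2 + T1) /
        (comp$pc1^2 + comp$pc2^2 + T1)
    sg <- (2 * comp$g1 * comp$g2 + T2) /
        (comp$g1^2 + comp$g2^2 + T2)
    pcm <- pmax(comp$pc1, comp$pc2)
    sum(spc * sg * pcm) / sum(pcm)
}

## ---- fitness dispersion ----------------------------------------------------

#' Sample standard deviation of repeated-run fitness values
#'
#' The stability measure of the repeated-run protocol: the sample
#' standard deviation (n-1 denominator) of the best fitness over runs.
#' Lower is more stable.
#'
#' @param values numeric vector, length >= 2.
#' @return nonnegative standard deviation.
#' @examples
#' fitnessStd(c(1, 2, 3))  # 1
#' @export
fitnessStd <- function(values) {
    if (!is.numeric(values) || length(values) < 2L)
        stop("at least two values are required")
    stats::sd(values)
}
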