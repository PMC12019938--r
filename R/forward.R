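# Forward imaging: camera frame stacks for the normal and spectral
# detection paths under sequential Hadamard illumination.

#' Virtual optical system constants
#'
#' @param magnification system magnification (default 10).
#' @param na objective numerical aperture (default 0.3).
#' @param cameraPixelUm camera pixel size, um (default 6.5).
#' @param demagnification illumination-path hologram demagnification
#'   (default 75).
#' @param laserNm excitation laser wavelength, nm (default 488).
#' @param detectionBandNm detection filter band, nm.
#' @return a list of constants; \code{effectivePixelUm} is
#'   \code{cameraPixelUm / magnification} (0.65 um for the defaults).
#' @export
systemConfig <- function(magnification = 10, na = 0.3, cameraPixelUm = 6.5,
                         demagnification = 75, laserNm = 488,
                         detectionBandNm = c(490, 700)) {
    list(magnification = magnification, na = na,
         cameraPixelUm = cameraPixelUm,
         effectivePixelUm = cameraPixelUm / magnification,
         demagnification = demagnification, laserNm = laserNm,
         detectionBandNm = detectionBandNm)
}

# Blur every illumination frame with the imaging PSF: IH' = IH * PSF_img.
blurredPatterns <- function(stack, psfImg) {
    fr <- frames(stack)
    d <- dim(fr)
    k <- kernelValues(psfImg)
    pl <- convPlan(d[1:2], dim(k))
    kf <- fftPad(k, pl)
    out <- array(0, d)
    for (kk in seq_len(d[3L]))
        out[, , kk] <- convWithPlan(fr[, , kk], pl, kf)
    out
}

#' Simulate the calibration acquisition in the normal path
#'
#' Frame \eqn{k} is the object times the blurred \eqn{k}th illumination
#' pattern: \eqn{I_P(x,y;k) = O(x,y) \times I_H'(x,y;k)} with
#' \eqn{I_H' = I_H * PSF_{img}}.
#'
#' @param object 2D non-negative object (matrix) matching the stack frame
#'   size; a uniform thin fluorescent layer for calibration.
#' @param stack a \linkS4class{PatternStack}.
#' @param psfImg imaging \linkS4class{Kernel2D}.
#' @return a \linkS4class{FrameStack} tagged \code{"normal"}.
#' @export
imageCalibrationStack <- function(object, stack, psfImg = gaussianPsf()) {
    stopifnot(is(stack, "PatternStack"), is(psfImg, "Kernel2D"))
    d <- dim(frames(stack))
    if (!all(dim(object) == d[1:2]))
        stop("shape mismatch: object does not match the pattern frames")
    ih <- blurredPatterns(stack, psfImg)
    out <- array(0, d)
    for (k in seq_len(d[3L]))
        out[, , k] <- object * ih[, , k]
    new("FrameStack", frames = pmax(out, 0), path = "normal")
}

#' Spectral-path calibration stack
#'
#' Convolves every normal-path calibration frame with the channel-averaged
#' spectral PSF, mimicking the wedge-prism dispersion recorded by the
#' monochrome camera: \eqn{I_{P,S}(\cdot;k) = I_P(\cdot;k) * Avg(PSF_{spectral})}.
#'
#' @param calStack the \linkS4class{FrameStack} from
#'   \code{\link{imageCalibrationStack}}.
#' @param avgSpec the averaged spectral \linkS4class{Kernel2D}
#'   (\code{\link{averageSpectralPsf}}).
#' @return a \linkS4class{FrameStack} tagged \code{"spectral"}.
#' @export
imageSpectralCalibrationStack <- function(calStack, avgSpec) {
    stopifnot(is(calStack, "FrameStack"), is(avgSpec, "Kernel2D"))
    fr <- frames(calStack)
    d <- dim(fr)
    k <- kernelValues(avgSpec)
    pl <- convPlan(d[1:2], dim(k))
    kf <- fftPad(k, pl)
    out <- array(0, d)
    for (kk in seq_len(d[3L]))
        out[, , kk] <- convWithPlan(fr[, , kk], pl, kf)
    new("FrameStack", frames = pmax(out, 0), path = "spectral")
}

#' Simulate tissue imaging in the normal path
#'
#' Frame \eqn{k} is the channel-averaged hyperspectral object times the
#' blurred pattern, convolved with the scattering PSF:
#' \eqn{I_T(\cdot;k) = [Avg_c(O_H) \times I_H'(\cdot;k)] * PSF_{scatter}}.
#'
#' @param truth the \linkS4class{HyperCube} ground truth \eqn{O_H}.
#' @param stack a \linkS4class{PatternStack}.
#' @param psfImg imaging \linkS4class{Kernel2D}.
#' @param psfScatter scattering \linkS4class{Kernel2D}.
#' @return a \linkS4class{FrameStack} tagged \code{"normal"}.
#' @export
imageTissueStack <- function(truth, stack, psfImg = gaussianPsf(),
                             psfScatter = deltaKernel()) {
    stopifnot(is(truth, "HyperCube"), is(stack, "PatternStack"),
              is(psfImg, "Kernel2D"), is(psfScatter, "Kernel2D"))
    d <- dim(frames(stack))
    cd <- dim(cubeData(truth))
    if (!all(cd[1:2] == d[1:2]))
        stop("shape mismatch: truth cube does not match pattern frames")
    avgO <- apply(cubeData(truth), c(1, 2), mean)
    ih <- blurredPatterns(stack, psfImg)
    ks <- kernelValues(psfScatter)
    pl <- convPlan(d[1:2], dim(ks))
    kf <- fftPad(ks, pl)
    out <- array(0, d)
    for (k in seq_len(d[3L]))
        out[, , k] <- convWithPlan(avgO * ih[, , k], pl, kf)
    new("FrameStack", frames = pmax(out, 0), path = "normal")
}

#' Simulate tissue imaging in the spectral path
#'
#' For each illumination frame \eqn{k} and channel \eqn{c}, the channel
#' image is modulated by the blurred pattern, convolved with the
#' channel-specific dispersed PSF, and the channel mean (the
#' wavelength-integrated image the monochrome camera records) is convolved
#' with the scattering PSF:
#' \deqn{I_{T,S}(\cdot;k,c) = [O_H(\cdot;c) \times I_H'(\cdot;k)] *
#'   PSF_{spectral}(\cdot;c) * PSF_{scatter}.}
#' The returned stack is \eqn{Avg_c(I_{T,S})}, size h x w x n.
#'
#' @param truth the \linkS4class{HyperCube} ground truth.
#' @param stack a \linkS4class{PatternStack}.
#' @param psfImg imaging \linkS4class{Kernel2D}.
#' @param psfSpectral a \linkS4class{SpectralKernelStack} with as many
#'   channels as the truth cube.
#' @param psfScatter scattering \linkS4class{Kernel2D}.
#' @return a \linkS4class{FrameStack} tagged \code{"spectral"}.
#' @export
imageTissueSpectralStack <- function(truth, stack, psfImg = gaussianPsf(),
                                     psfSpectral,
                                     psfScatter = deltaKernel()) {
    stopifnot(is(truth, "HyperCube"), is(stack, "PatternStack"),
              is(psfSpectral, "SpectralKernelStack"),
              is(psfScatter, "Kernel2D"))
    cube <- cubeData(truth)
    cd <- dim(cube)
    d <- dim(frames(stack))
    kern <- kernelValues(psfSpectral)
    C <- dim(kern)[3L]
    if (cd[3L] != C)
        stop("shape mismatch: truth channels != spectral PSF channels")
    if (!all(cd[1:2] == d[1:2]))
        stop("shape mismatch: truth cube does not match pattern frames")
    ih <- blurredPatterns(stack, psfImg)
    plS <- convPlan(d[1:2], dim(kern)[1:2])
    kfS <- lapply(seq_len(C), function(c) fftPad(kern[, , c], plS))
    ksc <- kernelValues(psfScatter)
    plSc <- convPlan(d[1:2], dim(ksc))
    kfSc <- fftPad(ksc, plSc)
    out <- array(0, d)
    for (k in seq_len(d[3L])) {
        acc <- matrix(0, d[1L], d[2L])
        for (c in seq_len(C))
            acc <- acc + convWithPlan(cube[, , c] * ih[, , k], plS, kfS[[c]])
        out[, , k] <- convWithPlan(acc / C, plSc, kfSc)
    }
    new("FrameStack", frames = pmax(out, 0), path = "spectral")
}

#' Apply Poisson shot noise to a frame stack
#'
#' Draws independent Poisson counts with mean intensity times
#' \code{photonsPerUnit} and rescales back to intensity units. Noise is off
#' in the headline simulations; this supports SNR experiments.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param photonsPerUnit expected photons per intensity unit (> 0).
#' @param seed RNG seed.
#' @return a \linkS4class{FrameStack} with the same path tag.
#' @export
addShotNoise <- function(stack, photonsPerUnit, seed = 1L) {
    stopifnot(is(stack, "FrameStack"))
    if (photonsPerUnit <= 0) stop("photonsPerUnit must be positive")
    fr <- frames(stack)
    noisy <- withSeed(seed, {
        counts <- stats::rpois(length(fr), lambda = fr * photonsPerUnit)
        array(counts / photonsPerUnit, dim(fr))
    })
    new("FrameStack", frames = noisy, path = stack@path)
}
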