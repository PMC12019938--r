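# Wide-field, optically sectioned and hyperspectral reconstruction, plus
# comparison metrics against ground truth.

#' Wide-field image from a frame stack
#'
#' The arithmetic mean over frames: sequential Hadamard illumination sums
#' to uniform illumination, so the frame mean is exactly the conventional
#' wide-field (scattering-blurred) image.
#'
#' @param stack a \linkS4class{FrameStack} or \linkS4class{PatternStack}.
#' @return numeric matrix.
#' @export
widefield <- function(stack) {
    fr <- frames(stack)
    apply(fr, c(1, 2), mean)
}

#' Optically sectioned image
#'
#' Decodes the stack, subtracts the per-pixel cross-talk offset, keeps only
#' digital-pinhole pixels (slice-wise multiplication with the mask),
#' averages over slices, and applies a Gaussian filter that suppresses the
#' periodic grid artifact between pinholes.
#'
#' @param stack the tissue \linkS4class{FrameStack} (normal path).
#' @param code the \linkS4class{IlluminationCode}.
#' @param pinholes a \linkS4class{PinholeMask} with matching geometry.
#' @param gridSigma sigma (px) of the grid-artifact Gaussian filter;
#'   default 3 (one cell). Use 0 to inspect the raw pinhole samples.
#' @return a \linkS4class{SectionedImage}.
#' @export
opticalSection <- function(stack, code, pinholes, gridSigma = 3) {
    stopifnot(is(stack, "FrameStack"), is(code, "IlluminationCode"),
              is(pinholes, "PinholeMask"))
    mask <- maskArray(pinholes)
    fr <- frames(stack)
    if (!all(dim(mask) == dim(fr)))
        stop("geometry mismatch: mask does not match the frame stack")
    dec <- decodedValues(decodeStack(stack, code))
    offset <- decodeOffsetImage(stack, codeOrder(code))
    sub <- sweep(dec, c(1, 2), offset)
    img <- apply(sub * mask, c(1, 2), mean)
    img <- pmax(img, 0)
    img <- gaussianBlur(img, gridSigma)
    new("SectionedImage", image = pmax(img, 0), gridSigma = gridSigma)
}

#' Slit-masked spectral projection
#'
#' Decodes the spectral-path stack, subtracts the per-pixel cross-talk
#' offset and multiplies slice-wise with the digital slit mask. The
#' resulting regularly aligned lines carry each pinhole's dispersed
#' spectrum.
#'
#' @param stackS the spectral-path tissue \linkS4class{FrameStack}.
#' @param code the \linkS4class{IlluminationCode}.
#' @param slits a \linkS4class{SlitMask}.
#' @return a \linkS4class{DecodedStack} (h x w x n), non-negative.
#' @export
spectralProjection <- function(stackS, code, slits) {
    stopifnot(is(stackS, "FrameStack"), is(code, "IlluminationCode"),
              is(slits, "SlitMask"))
    mask <- maskArray(slits)
    fr <- frames(stackS)
    if (!all(dim(mask) == dim(fr)))
        stop("geometry mismatch: slit mask does not match the frame stack")
    dec <- decodedValues(decodeStack(stackS, code))
    offset <- decodeOffsetImage(stackS, codeOrder(code))
    sub <- sweep(dec, c(1, 2), offset)
    new("DecodedStack", values = pmax(sub, 0) * mask, path = "spectral")
}

#' Reconstruct the hyperspectral cube from the spectral projection
#'
#' Rotates the spectral projection (bilinear) and the pinhole mask
#' (nearest-neighbor) by \code{angleDeg} about the frame center so the
#' dispersion lies along +x, then reads, for every pinhole pixel
#' \eqn{(x_0, y_0)} of rotated slice \eqn{k}, the C-long horizontal
#' intensity profile starting at \eqn{x_0} as that pixel's spectrum,
#' weighted by the rotated pinhole mask, and sums contributions over
#' \eqn{k}. The accumulated cube is de-rotated back to the original frame
#' and Gaussian-smoothed channel-wise to attenuate the periodic pinhole
#' grid.
#'
#' @param projection the \linkS4class{DecodedStack} from
#'   \code{\link{spectralProjection}}.
#' @param pinholes the \linkS4class{PinholeMask} (weighting function).
#' @param angleDeg rotation aligning the dispersion with +x; the negative
#'   of the dispersion angle (default 21).
#' @param channels number of spectral channels C.
#' @param gridSigma sigma (px) of the smoothing filter (default 3; 0
#'   disables).
#' @param wavelengthsNm wavelength axis for the cube (defaults to channel
#'   indices mapped over 490-700 nm).
#' @param edge \code{"skip"} (default) ignores pinholes whose profile would
#'   leave the rotated frame; \code{"error"} stops instead.
#' @return a \linkS4class{HyperCube} in the original (un-rotated) frame.
#' @export
reconstructHyperspectral <- function(projection, pinholes, angleDeg = 21.0,
                                     channels = 40L, gridSigma = 3,
                                     wavelengthsNm = NULL,
                                     edge = c("skip", "error")) {
    stopifnot(is(projection, "DecodedStack"), is(pinholes, "PinholeMask"))
    edge <- match.arg(edge)
    vals <- decodedValues(projection)
    mask <- maskArray(pinholes)
    if (!all(dim(mask) == dim(vals)))
        stop("geometry mismatch: pinhole mask does not match the projection")
    d <- dim(vals)
    C <- as.integer(channels)
    if (C > d[2L])
        stop("out-of-frame: more channels than frame width")
    n <- d[3L]
    cube <- array(0, c(d[1L], d[2L], C))
    for (k in seq_len(n)) {
        rotV <- rotateImage(vals[, , k], angleDeg, "bilinear")
        rotM <- rotateImage(mask[, , k], angleDeg, "nearest")
        ph <- which(rotM > 0, arr.ind = TRUE)
        if (nrow(ph) == 0L) next
        fits <- ph[, 2L] + C - 1L <= d[2L]
        if (edge == "error" && any(!fits))
            stop("out-of-frame: a spectral profile exits the rotated frame")
        ph <- ph[fits, , drop = FALSE]
        if (nrow(ph) == 0L) next
        w <- rotM[ph]
        for (cc in seq_len(C)) {
            cube[cbind(ph[, 1L], ph[, 2L], cc)] <-
                cube[cbind(ph[, 1L], ph[, 2L], cc)] +
                w * rotV[cbind(ph[, 1L], ph[, 2L] + cc - 1L)]
        }
    }
    # Back to the original orientation, then grid smoothing.
    out <- array(0, dim(cube))
    for (cc in seq_len(C)) {
        ch <- rotateImage(cube[, , cc], -angleDeg, "bilinear")
        if (gridSigma > 0) ch <- gaussianBlur(ch, gridSigma)
        out[, , cc] <- pmax(ch, 0)
    }
    if (is.null(wavelengthsNm))
        wavelengthsNm <- seq(490, 700, length.out = C)
    new("HyperCube", data = out, wavelengthsNm = wavelengthsNm)
}

#' Compare reconstructions against the ground truth
#'
#' Computes Pearson correlations of the wide-field and sectioned images
#' with the channel-averaged truth (excluding a border band), spectral
#' cosine similarities at the brightest pinhole-bearing pixels of the
#' recovered cube, and the background-suppression ratio (normalized
#' background energy of the sectioned image over that of the wide-field
#' image; below 1 means scattering was suppressed).
#'
#' @param wfImage wide-field matrix from \code{\link{widefield}}.
#' @param sectioned a \linkS4class{SectionedImage}.
#' @param hyper a \linkS4class{HyperCube} reconstruction (or NULL to skip
#'   spectral metrics).
#' @param truth the ground-truth \linkS4class{HyperCube}.
#' @param border border band width excluded from correlations (default 16).
#' @param nSamples number of spectral sample pixels (default 25).
#' @return a \linkS4class{MetricsReport}.
#' @export
compareToTruth <- function(wfImage, sectioned, hyper, truth, border = 16L,
                           nSamples = 25L) {
    stopifnot(is(sectioned, "SectionedImage"), is(truth, "HyperCube"))
    avgTruth <- apply(cubeData(truth), c(1, 2), mean)
    keep <- interiorMask(dim(avgTruth), border)
    secImg <- sectionedPixels(sectioned)
    wfCor <- safeCor(wfImage[keep], avgTruth[keep])
    osCor <- safeCor(secImg[keep], avgTruth[keep])
    cosines <- numeric(0)
    if (!is.null(hyper)) {
        hc <- cubeData(hyper)
        energy <- apply(hc, c(1, 2), sum)
        energy[!keep] <- 0
        ord <- order(energy, decreasing = TRUE)
        top <- ord[seq_len(min(nSamples, sum(energy > 0)))]
        if (length(top)) {
            rc <- arrayInd(top, dim(energy))
            cosines <- vapply(seq_len(nrow(rc)), function(i) {
                cosineSimilarity(hc[rc[i, 1L], rc[i, 2L], ],
                                 cubeData(truth)[rc[i, 1L], rc[i, 2L], ])
            }, numeric(1))
        }
    }
    # Background = dimmest truth pixels; energy fractions there.
    thr <- stats::quantile(avgTruth[keep], 0.25)
    bg <- keep & avgTruth <= thr
    bgFrac <- function(img) {
        tot <- sum(img[keep])
        if (tot <= 0) return(0)
        sum(img[bg]) / tot
    }
    wfBg <- bgFrac(wfImage)
    ratio <- if (wfBg > 0) bgFrac(secImg) / wfBg else 1
    new("MetricsReport", widefieldCor = wfCor, sectionedCor = osCor,
        spectralCosines = cosines, backgroundSuppression = ratio)
}

safeCor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
}
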