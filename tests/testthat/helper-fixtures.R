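# Shared fixtures, built lazily and cached for the whole run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name) {
    if (!exists(name, envir = .fixtureCache)) {
        value <- switch(name,
            code19 = illuminationCodeFor(19),
            code7 = illuminationCodeFor(7),
            stack19 = generatePatternStack(
                fixture("code19"), assignCodes(19, 5, 19, 19)),
            # 128 px scene shared by calibration/reconstruction tests.
            scene = buildScene(),
            scatterKernel = monteCarloScatterPsf(
                scatterParams(photons = 2e5, seed = 42)),
            stop("unknown fixture: ", name))
        assign(name, value, envir = .fixtureCache)
    }
    get(name, envir = .fixtureCache)
}

buildScene <- function() {
    n <- 19L; q <- 5L; cell <- 3L; W <- 128L; H <- 128L; C <- 40L
    code <- fixture("code19")
    layout <- layoutForFrame(n, q, W, H, cell)
    stack <- generatePatternStack(code, layout)
    psfImg <- gaussianPsf(0.54)
    psfSpec <- spectralPsf(psfImg, lengthPx = 40, angleDeg = -21,
                           channels = C)
    calStack <- imageCalibrationStack(matrix(1, H, W), stack, psfImg)
    pinholes <- binarizePinholes(decodeStack(calStack, code), code)
    calSpec <- imageSpectralCalibrationStack(calStack,
                                             averageSpectralPsf(psfSpec))
    slits <- digitalSlits(calSpec, code, lengthPx = 40, angleDeg = -21)
    list(n = n, q = q, cell = cell, W = W, H = H, C = C, code = code,
         layout = layout, stack = stack, psfImg = psfImg,
         psfSpec = psfSpec, calStack = calStack, pinholes = pinholes,
         slits = slits)
}

# Direct shift-and-add "same" convolution with zero padding: the
# independent oracle for the FFT convolution used by the forward model.
naiveConvolveSame <- function(img, kernel) {
    h <- nrow(img); w <- ncol(img)
    kh <- nrow(kernel); kw <- ncol(kernel)
    cr <- (kh + 1L) %/% 2L; cc <- (kw + 1L) %/% 2L
    out <- matrix(0, h, w)
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
        kv <- kernel[a, b]
        if (kv == 0) next
        dr <- a - cr; dc <- b - cc
        rs <- max(1L, 1L + dr):min(h, h + dr)
        cs <- max(1L, 1L + dc):min(w, w + dc)
        out[rs, cs] <- out[rs, cs] +
            kv * img[rs - dr, cs - dc, drop = FALSE]
    }
    out
}

# Centered crop of a square matrix to (2 * half + 1) pixels.
centerCrop <- function(m, half) {
    ctr <- (nrow(m) + 1L) %/% 2L
    m[(ctr - half):(ctr + half), (ctr - half):(ctr + half)]
}

cosSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
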