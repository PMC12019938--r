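# Point spread functions: Gaussian imaging PSF, Monte Carlo tissue
# scattering PSF, spectrally dispersed PSF stack.

#' Discretized isotropic Gaussian imaging PSF
#'
#' Midpoint-discretized Gaussian on an odd square support, normalized to
#' unit sum. The default sigma of 0.54 pixels models a diffraction-limited
#' spot sampled at the 0.65 um effective pixel of the virtual setup.
#'
#' @param sigmaPx standard deviation in pixels (default 0.54).
#' @param radius support radius in pixels; defaults to
#'   \code{max(1, ceiling(4 * sigmaPx))}.
#' @return a \linkS4class{Kernel2D} of size \code{2 * radius + 1}.
#' @examples
#' k <- gaussianPsf(0.54)
#' sum(kernelValues(k))  # 1
#' @export
gaussianPsf <- function(sigmaPx = 0.54, radius = NULL) {
    if (sigmaPx <= 0) stop("sigmaPx must be positive")
    if (is.null(radius)) radius <- max(1L, ceiling(4 * sigmaPx))
    x <- (-radius):radius
    g <- exp(-x^2 / (2 * sigmaPx^2))
    k <- outer(g, g)
    new("Kernel2D", values = k / sum(k))
}

#' Delta (identity) kernel
#'
#' @param radius support radius; the kernel is all zero except a unit
#'   center.
#' @return a \linkS4class{Kernel2D}.
#' @export
deltaKernel <- function(radius = 0L) {
    n <- 2L * radius + 1L
    v <- matrix(0, n, n)
    v[radius + 1L, radius + 1L] <- 1
    new("Kernel2D", values = v)
}

#' Monte Carlo scattering parameters
#'
#' Defaults describe sectioned tissue imaged at modest depth: scattering
#' coefficient 100 cm^-1, absorption 0.1 cm^-1, Henyey-Greenstein
#' anisotropy 0.9, emitter depth 50 um, collection NA 0.3,
#' excitation/emission 488/550 nm, 0.65 um pixels.
#'
#' @param mus scattering coefficient, cm^-1.
#' @param mua absorption coefficient, cm^-1.
#' @param g anisotropy factor.
#' @param depthUm emitter depth, um.
#' @param na collection numerical aperture.
#' @param lambdaExNm,lambdaEmNm wavelengths, nm (bookkeeping; only the
#'   emission path is simulated).
#' @param photons photon budget (at least 1e4; default 1e6).
#' @param pixelUm pixel size at the sample, um.
#' @param seed RNG seed.
#' @return a \linkS4class{ScatterParams}.
#' @export
scatterParams <- function(mus = 100, mua = 0.1, g = 0.9, depthUm = 50,
                          na = 0.3, lambdaExNm = 488, lambdaEmNm = 550,
                          photons = 1e6, pixelUm = 0.65, seed = 1L) {
    new("ScatterParams", mus = mus, mua = mua, g = g, depthUm = depthUm,
        na = na, lambdaExNm = lambdaExNm, lambdaEmNm = lambdaEmNm,
        photons = photons, pixelUm = pixelUm, seed = as.integer(seed))
}

#' Sample photon free-path lengths
#'
#' Exponential step lengths with mean free path \eqn{1/\mu_s} (100 um for
#' \eqn{\mu_s = 100} cm^-1), as drawn inside the Monte Carlo transport loop.
#'
#' @param n number of samples.
#' @param mus scattering coefficient in cm^-1.
#' @param seed optional RNG seed.
#' @return numeric vector of path lengths in micrometers.
#' @export
sampleFreePaths <- function(n, mus, seed = NULL) {
    musUm <- mus / 1e4                     # cm^-1 -> um^-1
    if (is.null(seed)) stats::rexp(n, rate = musUm)
    else withSeed(seed, stats::rexp(n, rate = musUm))
}

# Henyey-Greenstein cosine sampling (vectorized).
sampleHG <- function(n, g) {
    u <- stats::runif(n)
    if (g < 1e-6) return(2 * u - 1)
    f <- (1 - g^2) / (1 - g + 2 * g * u)
    (1 + g^2 - f^2) / (2 * g)
}

# Rotate unit direction vectors by polar angle acos(cosT) about themselves
# with azimuth phi (standard scattering update, vectorized).
scatterDirections <- function(ux, uy, uz, cosT, phi) {
    sinT <- sqrt(pmax(0, 1 - cosT^2))
    cosP <- cos(phi); sinP <- sin(phi)
    near <- abs(uz) > 0.99999
    denom <- sqrt(pmax(1e-12, 1 - uz^2))
    nx <- sinT * (ux * uz * cosP - uy * sinP) / denom + ux * cosT
    ny <- sinT * (uy * uz * cosP + ux * sinP) / denom + uy * cosT
    nz <- -sinT * cosP * denom + uz * cosT
    # Degenerate case: direction along +-z.
    nx[near] <- (sinT * cosP)[near]
    ny[near] <- (sinT * sinP)[near]
    nz[near] <- (sign(uz) * cosT)[near]
    norm <- sqrt(nx^2 + ny^2 + nz^2)
    list(ux = nx / norm, uy = ny / norm, uz = nz / norm)
}

#' Monte Carlo tissue-scattering PSF
#'
#' Simulates isotropic point emitters at the stated depth below the tissue
#' surface. Photons take exponential steps (mean free path \eqn{1/\mu_s})
#' with Henyey-Greenstein angular scattering and continuous absorption
#' weighting \eqn{e^{-\mu_a s}}; a photon reaching the surface within the
#' collection NA cone is recorded. Ballistic (never-scattered) photons are
#' binned at the origin -- the objective refocuses them to the emitter's
#' conjugate image point -- while scattered photons are binned at their
#' surface exit position, forming the halo. The exit histogram is truncated
#' where cumulative energy reaches 99.9 % and renormalized.
#'
#' @param params a \linkS4class{ScatterParams}.
#' @return a \linkS4class{Kernel2D} on the pixel grid of
#'   \code{params@pixelUm}.
#' @export
monteCarloScatterPsf <- function(params = scatterParams()) {
    stopifnot(is(params, "ScatterParams"))
    withSeed(params@seed, .mcScatterRun(params))
}

.mcScatterRun <- function(params) {
    musUm <- params@mus / 1e4
    muaUm <- params@mua / 1e4
    nPhot <- as.integer(params@photons)
    # Histogram extent: four times the emitter depth covers the collected
    # halo; photons exiting further out are discarded before the 99.9 %
    # energy trim.
    maxR <- params@depthUm * 4
    half <- ceiling(maxR / params@pixelUm)
    size <- 2L * half + 1L
    hist <- matrix(0, size, size)
    thetaMax <- asin(min(1, params@na))
    cosMin <- cos(thetaMax)
    # Isotropic emission over the full sphere.
    uz <- stats::runif(nPhot, -1, 1)
    phi <- stats::runif(nPhot, 0, 2 * pi)
    sinTh <- sqrt(1 - uz^2)
    ux <- sinTh * cos(phi); uy <- sinTh * sin(phi)
    x <- numeric(nPhot); y <- numeric(nPhot)
    z <- rep(params@depthUm, nPhot)       # z = depth below surface, z=0 top
    w <- rep(1, nPhot)
    nScat <- integer(nPhot)
    zKill <- params@depthUm + 10 / musUm  # photons too deep are lost
    maxSteps <- 400L
    exitX <- numeric(0); exitY <- numeric(0); exitW <- numeric(0)
    exitBallistic <- logical(0)
    for (step in seq_len(maxSteps)) {
        m <- length(x)
        if (m == 0L) break
        s <- stats::rexp(m, rate = musUm)
        # Photons crossing the surface (z -> <= 0) during this step exit.
        up <- uz < 0
        tSurf <- ifelse(up, z / (-uz), Inf)
        exits <- up & tSurf <= s
        if (any(exits)) {
            t0 <- tSurf[exits]
            wx <- w[exits] * exp(-muaUm * t0)
            ok <- (-uz[exits]) >= cosMin        # within the NA cone
            exitX <- c(exitX, (x[exits] + ux[exits] * t0)[ok])
            exitY <- c(exitY, (y[exits] + uy[exits] * t0)[ok])
            exitW <- c(exitW, wx[ok])
            exitBallistic <- c(exitBallistic, (nScat[exits] == 0L)[ok])
        }
        keep <- !exits
        x <- (x + ux * s)[keep]; y <- (y + uy * s)[keep]
        z <- (z + uz * s)[keep]
        w <- (w * exp(-muaUm * s))[keep]
        ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]
        nScat <- nScat[keep] + 1L
        alive <- z < zKill & w > 1e-4
        x <- x[alive]; y <- y[alive]; z <- z[alive]; w <- w[alive]
        ux <- ux[alive]; uy <- uy[alive]; uz <- uz[alive]
        nScat <- nScat[alive]
        m <- length(x)
        if (m == 0L) break
        cosT <- sampleHG(m, params@g)
        newDir <- scatterDirections(ux, uy, uz, cosT,
                                    stats::runif(m, 0, 2 * pi))
        ux <- newDir$ux; uy <- newDir$uy; uz <- newDir$uz
    }
    if (length(exitW) == 0L)
        stop("zero acceptance: no photon reached the surface within the NA ",
             "cone (pathological parameters?)")
    bx <- ifelse(exitBallistic, 0, exitX)
    by <- ifelse(exitBallistic, 0, exitY)
    cx <- round(bx / params@pixelUm)
    cy <- round(by / params@pixelUm)
    inb <- abs(cx) <= half & abs(cy) <= half
    cx <- cx[inb] + half + 1L
    cy <- cy[inb] + half + 1L
    exitW <- exitW[inb]
    lin <- (cx - 1L) * size + cy
    add <- tapply(exitW, lin, sum)
    hist[as.integer(names(add))] <- as.numeric(add)
    trimKernel(hist / sum(hist), keep = 0.999)
}

# Crop a centered square kernel to the smallest odd support holding `keep`
# of the energy, then renormalize.
trimKernel <- function(k, keep = 0.999) {
    size <- nrow(k)
    half <- (size - 1L) %/% 2L
    ctr <- half + 1L
    for (r in 0:half) {
        rows <- (ctr - r):(ctr + r)
        if (sum(k[rows, rows]) >= keep) {
            k <- k[rows, rows, drop = FALSE]
            return(new("Kernel2D", values = k / sum(k)))
        }
    }
    new("Kernel2D", values = k / sum(k))
}

#' Spectrally dispersed PSF stack
#'
#' Channel \eqn{c} of the stack is the base imaging kernel translated by
#' \eqn{(c-1)/(C-1)} of the dispersion length along the dispersion angle
#' (counter-clockwise positive from the +x axis; the default -21 degrees
#' points right-and-down in image coordinates). Channel 1 is unshifted.
#' Sub-pixel displacements use bilinear interpolation. The defaults model a
#' 26 um dispersion (40 px at 0.65 um pixels) from the wedge prism.
#'
#' @param base a \linkS4class{Kernel2D} (typically \code{gaussianPsf()}).
#' @param lengthPx maximum dispersion length in pixels (default 40).
#' @param angleDeg dispersion angle in degrees (default -21).
#' @param channels number of spectral channels (default 40).
#' @return a \linkS4class{SpectralKernelStack}; warns when channel spacing
#'   falls below one pixel.
#' @export
spectralPsf <- function(base = gaussianPsf(), lengthPx = 40,
                        angleDeg = -21.0, channels = 40L) {
    stopifnot(is(base, "Kernel2D"))
    channels <- as.integer(channels)
    if (channels < 1L) stop("channels must be >= 1")
    if (channels >= 2L && lengthPx / channels < 1)
        warning("sub-pixel channel spacing: dispersion length per channel ",
                "below one pixel")
    bk <- kernelValues(base)
    supp <- nrow(bk) + 2L * ceiling(abs(lengthPx)) + 3L
    if (supp %% 2L == 0L) supp <- supp + 1L
    a <- angleDeg * pi / 180
    disp <- if (channels == 1L) 0 else
        (seq_len(channels) - 1) / (channels - 1) * lengthPx
    dCol <- disp * cos(a)
    dRow <- -disp * sin(a)                 # +angle is counter-clockwise
    kern <- array(0, c(supp, supp, channels))
    for (c in seq_len(channels)) {
        k <- shiftIntoSupport(bk, supp, dRow[c], dCol[c])
        kern[, , c] <- k / sum(k)
    }
    new("SpectralKernelStack", kernels = kern, lengthPx = lengthPx,
        angleDeg = angleDeg, displacements = cbind(dCol = dCol, dRow = dRow))
}

#' Average a spectral PSF stack over the spectral dimension
#'
#' The camera in the spectral path records the wavelength-integrated image;
#' the corresponding kernel is the channel mean, an elongated profile tilted
#' at the dispersion angle.
#'
#' @param stack a \linkS4class{SpectralKernelStack}.
#' @return a \linkS4class{Kernel2D} (unit sum).
#' @export
averageSpectralPsf <- function(stack) {
    stopifnot(is(stack, "SpectralKernelStack"))
    k <- apply(kernelValues(stack), c(1, 2), mean)
    new("Kernel2D", values = k / sum(k))
}

#' Principal-axis orientation of a kernel
#'
#' Orientation (degrees, counter-clockwise from the +x axis, in
#' (-90, 90]) of the leading eigenvector of the intensity-weighted
#' second-moment tensor. Used to confirm the tilt of the averaged spectral
#' PSF.
#'
#' @param kernel a \linkS4class{Kernel2D}.
#' @return angle in degrees.
#' @export
kernelOrientation <- function(kernel) {
    v <- kernelValues(kernel)
    n <- nrow(v)
    ctr <- (n + 1) / 2
    xs <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
    ys <- matrix(ctr - seq_len(n), n, n)    # y up
    w <- v / sum(v)
    mx <- sum(w * xs); my <- sum(w * ys)
    cxx <- sum(w * (xs - mx)^2)
    cyy <- sum(w * (ys - my)^2)
    cxy <- sum(w * (xs - mx) * (ys - my))
    e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2))
    ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    ang
}

#' Centroid of a kernel in (dCol, dRow) pixel offsets from its center
#'
#' @param kernel a \linkS4class{Kernel2D} or a numeric matrix.
#' @return numeric \code{c(dCol, dRow)}.
#' @export
kernelCentroid <- function(kernel) {
    v <- if (is(kernel, "Kernel2D")) kernelValues(kernel) else kernel
    ctr <- (dim(v) + 1) / 2
    w <- v / sum(v)
    rows <- matrix(seq_len(nrow(v)), nrow(v), ncol(v))
    cols <- matrix(seq_len(ncol(v)), nrow(v), ncol(v), byrow = TRUE)
    c(dCol = sum(w * cols) - ctr[2], dRow = sum(w * rows) - ctr[1])
}
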