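# Synthetic multi-channel phantoms, dye spectra and hyperspectral ground
# truth. Stands in for stained-tissue confocal data: channel 1 mimics a
# nuclear stain, channel 2 a filamentous cytoskeletal marker, channels 3-4
# ramified cell bodies.

addDisk <- function(img, r0, c0, radius, amp) {
    h <- nrow(img); w <- ncol(img)
    rr <- max(1, floor(r0 - 3 * radius)):min(h, ceiling(r0 + 3 * radius))
    cc <- max(1, floor(c0 - 3 * radius)):min(w, ceiling(c0 + 3 * radius))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    # Soft-edged disk: flat core with a Gaussian skirt.
    prof <- amp * pmin(1, exp(-(sqrt(d2) - radius) / (0.35 * radius)))
    prof[sqrt(d2) <= radius] <- amp
    img[rr, cc] <- img[rr, cc] + prof
    img
}

drawFilament <- function(img, nSteps, amp) {
    h <- nrow(img); w <- ncol(img)
    r <- stats::runif(1, 1, h); c <- stats::runif(1, 1, w)
    ang <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(0, nSteps, 2)
    for (s in seq_len(nSteps)) {
        ang <- ang + stats::rnorm(1, 0, 0.25)
        r <- r + sin(ang); c <- c + cos(ang)
        r <- min(max(r, 1), h); c <- min(max(c, 1), w)
        pts[s, ] <- c(r, c)
    }
    ri <- round(pts[, 1]); ci <- round(pts[, 2])
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    img[cbind(ri[ok], ci[ok])] <- img[cbind(ri[ok], ci[ok])] + amp
    img
}

addBlob <- function(img, r0, c0, radius, arms, amp) {
    img <- addDisk(img, r0, c0, radius, amp)
    for (a in seq_len(arms)) {
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, radius, 3 * radius)
        nPts <- ceiling(len)
        t <- seq(0, len, length.out = nPts)
        rr <- round(r0 + t * sin(ang)); cc <- round(c0 + t * cos(ang))
        ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
        img[cbind(rr[ok], cc[ok])] <- img[cbind(rr[ok], cc[ok])] +
            amp * 0.7
    }
    img
}

#' Generate a synthetic multi-channel phantom
#'
#' Channel 1 holds disk-like nuclei, channel 2 curvilinear filaments, and
#' channels 3-4 ramified blobs, emulating a 4-marker stained tissue section.
#' Intensities are arbitrary linear fluorescence units. Deterministic under
#' \code{seed}.
#'
#' @param width,height frame size in pixels, at least 64.
#' @param seed RNG seed.
#' @param style \code{"mixed"} (all structures, default) or a single
#'   structure class (\code{"nuclei"}, \code{"filaments"}, \code{"blobs"});
#'   single-structure styles leave the other channels empty.
#' @return a \linkS4class{MultiChannelPhantom}.
#' @examples
#' ph <- makePhantom(64, 64, seed = 1)
#' dim(phantomImage(ph))
#' @export
makePhantom <- function(width, height, seed = 1L,
                        style = c("mixed", "nuclei", "filaments", "blobs")) {
    style <- match.arg(style)
    width <- as.integer(width); height <- as.integer(height)
    if (width < 64L || height < 64L)
        stop("phantom dimensions must be at least 64 px")
    withSeed(seed, {
        img <- array(0, c(height, width, 4L))
        area <- width * height
        if (style %in% c("mixed", "nuclei")) {
            nNuc <- max(4L, round(area / 2500))
            ch <- matrix(0, height, width)
            for (i in seq_len(nNuc))
                ch <- addDisk(ch, stats::runif(1, 1, height),
                              stats::runif(1, 1, width),
                              stats::runif(1, 4, 8),
                              stats::runif(1, 0.6, 1))
            img[, , 1L] <- ch
        }
        if (style %in% c("mixed", "filaments")) {
            nFil <- max(3L, round(area / 4000))
            ch <- matrix(0, height, width)
            for (i in seq_len(nFil))
                ch <- drawFilament(ch, nSteps = round(0.7 * max(width,
                                                                height)),
                                   amp = 1)
            ch <- pmax(0, gaussianBlur(ch, 2 / 2.355))
            img[, , 2L] <- ch / max(ch)
        }
        if (style %in% c("mixed", "blobs")) {
            for (chan in 3:4) {
                nBlob <- max(3L, round(area / 5000))
                ch <- matrix(0, height, width)
                for (i in seq_len(nBlob))
                    ch <- addBlob(ch, stats::runif(1, 1, height),
                                  stats::runif(1, 1, width),
                                  stats::runif(1, 2.5, 5),
                                  arms = sample(3:6, 1),
                                  amp = stats::runif(1, 0.5, 1))
                img[, , chan] <- ch / max(ch)
            }
        }
        new("MultiChannelPhantom", image = img,
            labels = c("nuclei", "filaments", "blobs1", "blobs2"))
    })
}

#' Synthetic dye emission spectra
#'
#' Four unimodal, red-skewed emission peaks spread over the detection band,
#' ordered by peak wavelength and row-normalized to unit sum. These are
#' parameterized stand-ins for measured dye spectra (a CSV loader,
#' \code{\link{readSpectraCSV}}, accepts real tabulated curves); the band
#' default matches a 490-700 nm detection filter, which clips any emission
#' below its blue edge.
#'
#' @param channels number of spectral channels, at least 4 (default 40).
#' @param rangeNm detection band, nm (default \code{c(490, 700)}).
#' @param peaksNm peak wavelengths of the four dyes.
#' @param widthsNm Gaussian core widths, nm.
#' @param skew right-tail skew factors.
#' @return an \linkS4class{EmissionSpectra}.
#' @export
dyeSpectra <- function(channels = 40L, rangeNm = c(490, 700),
                       peaksNm = c(505, 545, 600, 665),
                       widthsNm = c(18, 22, 26, 28),
                       skew = c(3, 3, 3, 3)) {
    channels <- as.integer(channels)
    if (channels < 4L) stop("channels must be >= 4")
    wl <- seq(rangeNm[1L], rangeNm[2L], length.out = channels)
    Fm <- t(vapply(seq_along(peaksNm), function(d) {
        z <- (wl - peaksNm[d]) / widthsNm[d]
        # Skew-normal shaped emission: sharp blue edge, long red tail.
        v <- exp(-z^2 / 2) * stats::pnorm(skew[d] * z) * 2
        v / sum(v)
    }, numeric(channels)))
    new("EmissionSpectra", spectra = Fm, wavelengthsNm = wl)
}

#' Synthesize the hyperspectral ground truth by linear mixing
#'
#' \eqn{O_H[x, y, c] = \sum_d I_R[x, y, d] \, F[d, c]}: each pixel's
#' spectrum is the abundance-weighted mix of the dye spectra. With unit-sum
#' spectra the channel sum at each pixel equals the channel sum of the
#' phantom (mass conservation).
#'
#' @param phantom a \linkS4class{MultiChannelPhantom}.
#' @param spectra an \linkS4class{EmissionSpectra} with one row per phantom
#'   channel.
#' @return a \linkS4class{HyperCube}.
#' @export
synthHyperspectral <- function(phantom, spectra) {
    stopifnot(is(phantom, "MultiChannelPhantom"),
              is(spectra, "EmissionSpectra"))
    img <- phantomImage(phantom)
    Fm <- spectraMatrix(spectra)
    d <- dim(img)
    if (d[3L] != nrow(Fm))
        stop("shape mismatch: phantom channels != spectra rows")
    flat <- matrix(img, d[1L] * d[2L], d[3L])
    cube <- array(flat %*% Fm, c(d[1L], d[2L], ncol(Fm)))
    new("HyperCube", data = cube, wavelengthsNm = wavelengths(spectra))
}

#' Uniform broadband calibration phantom
#'
#' A thin, spatially uniform, spectrally flat fluorescent layer -- the
#' object used to calibrate digital pinhole and slit positions.
#'
#' @param width,height frame size in pixels, at least 64.
#' @param channels number of spectral channels.
#' @param rangeNm wavelength band, nm.
#' @return a \linkS4class{HyperCube} with every pixel and channel identical.
#' @export
calibrationPhantom <- function(width, height, channels = 40L,
                               rangeNm = c(490, 700)) {
    width <- as.integer(width); height <- as.integer(height)
    if (width < 64L || height < 64L)
        stop("calibration phantom dimensions must be at least 64 px")
    new("HyperCube",
        data = array(1, c(height, width, as.integer(channels))),
        wavelengthsNm = seq(rangeNm[1L], rangeNm[2L],
                            length.out = as.integer(channels)))
}

#' Recover dye abundances from a hyperspectral cube by least squares
#'
#' Given the (full-row-rank) spectra matrix, solves the per-pixel linear
#' mixing model for the abundances; exact in the noiseless case.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @param spectra the \linkS4class{EmissionSpectra} used for mixing.
#' @return numeric array (h x w x dyes).
#' @export
unmixAbundances <- function(cube, spectra) {
    Fm <- spectraMatrix(spectra)
    d <- dim(cubeData(cube))
    flat <- matrix(cubeData(cube), d[1L] * d[2L], d[3L])
    ab <- t(solve(Fm %*% t(Fm), Fm %*% t(flat)))
    array(ab, c(d[1L], d[2L], nrow(Fm)))
}
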