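# Phase-only hologram design (Gerchberg-Saxton), Fraunhofer propagation,
# speckle suppression by pattern-preserving shift averaging.

fftShift <- function(x) {
    h <- nrow(x); w <- ncol(x)
    x[c((h %/% 2 + 1):h, 1:(h %/% 2)), c((w %/% 2 + 1):w, 1:(w %/% 2))]
}

ifftShift <- function(x) {
    h <- nrow(x); w <- ncol(x)
    x[c((h - h %/% 2 + 1):h, 1:(h - h %/% 2)),
      c((w - w %/% 2 + 1):w, 1:(w - w %/% 2))]
}

# Unitary centered 2D DFT and inverse: Parseval holds exactly.
unitaryFFT <- function(x) fftShift(stats::fft(ifftShift(x))) / sqrt(length(x))
unitaryIFFT <- function(x)
    fftShift(stats::fft(ifftShift(x), inverse = TRUE)) / sqrt(length(x))

#' Metasurface aperture plan
#'
#' @param diameterUm metasurface diameter in micrometers (default 100).
#' @param pitchNm meta-atom pitch in nanometers (default 330).
#' @param wavelengthNm operating wavelength in nanometers (default 488).
#' @return an \linkS4class{AperturePlan}; the grid holds
#'   \code{floor(diameter/pitch)} meta-atoms per side (303 for the
#'   defaults).
#' @export
aperturePlan <- function(diameterUm = 100, pitchNm = 330,
                         wavelengthNm = 488) {
    new("AperturePlan", diameterUm = diameterUm, pitchNm = pitchNm,
        wavelengthNm = wavelengthNm,
        atomsPerSide = as.integer(floor(diameterUm * 1e3 / pitchNm)))
}

circularAperture <- function(gridSize, atomsPerSide) {
    ctr <- (gridSize + 1) / 2
    r <- atomsPerSide / 2
    d <- outer(seq_len(gridSize) - ctr, seq_len(gridSize) - ctr,
               function(y, x) sqrt(x^2 + y^2))
    d <= r
}

#' Gerchberg-Saxton phase retrieval for a binary target pattern
#'
#' Alternating projections between the aperture constraint (unit amplitude
#' inside the circular aperture, seeded random initial phase) and the
#' far-field amplitude constraint (square root of the target, scaled to the
#' aperture energy). The Fourier-magnitude RMS error is non-increasing over
#' iterations, the classical error-reduction property.
#'
#' The optimization grid equals the target frame, which must be at least as
#' large as the meta-atom grid (\code{atomsPerSide} of the plan).
#'
#' @param target binary matrix (the pattern the far field should form); must
#'   contain at least one nonzero pixel.
#' @param plan an \linkS4class{AperturePlan}.
#' @param iterations number of GS iterations (default 100).
#' @param seed RNG seed for the initial phase.
#' @return a \linkS4class{PhaseMap}; \code{iterationErrors()} exposes the
#'   per-iteration error sequence.
#' @seealso \code{\link{fraunhoferPropagate}}, \code{\link{speckleAverage}}
#' @export
gerchbergSaxton <- function(target, plan = aperturePlan(),
                            iterations = 100L, seed = 1L) {
    stopifnot(is.matrix(target), is(plan, "AperturePlan"))
    if (iterations < 1L) stop("iterations must be >= 1")
    if (all(target == 0))
        stop("zero target: an all-dark target has no phase solution")
    N <- nrow(target)
    if (N != ncol(target)) stop("target must be square")
    if (N < plan@atomsPerSide)
        stop("target frame (", N, ") smaller than the meta-atom grid (",
             plan@atomsPerSide, ")")
    aper <- circularAperture(N, plan@atomsPerSide)
    aperAmp <- ifelse(aper, 1, 0)
    energy <- sum(aperAmp^2)
    targetAmp <- sqrt(target)
    targetAmp <- targetAmp * sqrt(energy / sum(targetAmp^2))
    phase <- withSeed(seed, matrix(stats::runif(N * N, 0, 2 * pi), N, N))
    field <- aperAmp * exp(1i * phase)
    errs <- numeric(iterations)
    for (it in seq_len(iterations)) {
        FF <- unitaryFFT(field)
        errs[it] <- sqrt(mean((Mod(FF) - targetAmp)^2))
        FF <- targetAmp * exp(1i * Arg(FF))
        back <- unitaryIFFT(FF)
        phase <- Arg(back) %% (2 * pi)
        field <- aperAmp * exp(1i * phase)
    }
    phase[!aper] <- 0
    new("PhaseMap", phase = phase, aperture = aperAmp, target = target,
        plan = plan, errors = errs, seed = as.integer(seed))
}

#' Fraunhofer far-field propagation of a phase-only aperture field
#'
#' The far-field intensity is the squared magnitude of the unitary centered
#' discrete Fourier transform of the unit-amplitude, phase-modulated
#' aperture field. Total intensity equals the aperture energy (Parseval).
#'
#' @param phase a \linkS4class{PhaseMap}.
#' @return a \linkS4class{HologramImage}.
#' @export
fraunhoferPropagate <- function(phase) {
    stopifnot(is(phase, "PhaseMap"))
    field <- phase@aperture * exp(1i * phaseValues(phase))
    FF <- unitaryFFT(field)
    new("HologramImage", intensity = Mod(FF)^2,
        apertureEnergy = sum(Mod(field)^2))
}

#' Speckle suppression by averaging pattern-preserving shifted holograms
#'
#' Coherent holograms carry speckle. Shifting the hologram by a full
#' self-similarity period (a multiple of \eqn{n} cells along the
#' \code{\link{selfSimilarityShift}} direction) leaves the periodic target
#' pattern unchanged while moving the speckle grain, so averaging
#' \code{count} shifted copies reduces speckle contrast roughly as
#' \eqn{1/\sqrt{count}}. In hardware the shifts are stage moves.
#'
#' Shifts wrap circularly, so the frame dimensions must be multiples of the
#' pattern period along the shifted axes; the shift is verified against the
#' stored target and rejected otherwise.
#'
#' @param phase a \linkS4class{PhaseMap}.
#' @param shiftPx integer pixel shift \code{c(dRow, dCol)} applied
#'   cumulatively between copies; must leave the target invariant. For a
#'   layout with cell size \code{cellPx} the full period is
#'   \code{n * cellPx} pixels along the self-similarity direction.
#' @param count number of copies averaged (default 4, giving the 76-frame
#'   budget of a 19-pattern cycle).
#' @return a \linkS4class{HologramImage}.
#' @export
speckleAverage <- function(phase, shiftPx, count = 4L) {
    stopifnot(is(phase, "PhaseMap"))
    count <- as.integer(count)
    if (count < 1L) stop("count must be >= 1")
    holo <- fraunhoferPropagate(phase)
    I <- hologramIntensity(holo)
    if (count == 1L) return(holo)
    shiftPx <- as.integer(round(shiftPx))
    tgt <- phase@target
    if (!all(translatePeriodic(tgt, shiftPx[1L], shiftPx[2L]) == tgt))
        stop("shift-period error: the requested shift does not preserve ",
             "the target pattern")
    acc <- I
    cur <- I
    for (t in seq_len(count - 1L)) {
        cur <- translatePeriodic(cur, shiftPx[1L], shiftPx[2L])
        acc <- acc + cur
    }
    new("HologramImage", intensity = acc / count,
        apertureEnergy = holo@apertureEnergy)
}

#' Speckle contrast over a region
#'
#' Standard deviation over mean of the intensity restricted to \code{region}
#' (e.g. the on-cells of the target pattern).
#'
#' @param holo a \linkS4class{HologramImage}.
#' @param region logical matrix selecting pixels.
#' @return numeric contrast.
#' @export
speckleContrast <- function(holo, region) {
    v <- hologramIntensity(holo)[region]
    stats::sd(v) / mean(v)
}

#' Holographic viewing angle of a periodic modulator
#'
#' \eqn{\theta = 2 \arcsin(\lambda / 2p)} in degrees, for pitch \eqn{p} and
#' wavelength \eqn{\lambda}. Sub-wavelength meta-atom pitches give wide
#' angles (above 75 degrees for 488 nm light on a 330 nm pitch), unlike
#' conventional spatial light modulators.
#'
#' @param pitchNm modulator pitch in nanometers.
#' @param wavelengthNm wavelength in nanometers; must not exceed twice the
#'   pitch (evanescent otherwise).
#' @return angle in degrees.
#' @examples
#' viewingAngle(330, 488)
#' @export
viewingAngle <- function(pitchNm, wavelengthNm) {
    if (wavelengthNm > 2 * pitchNm)
        stop("domain error: wavelength exceeds twice the pitch ",
             "(evanescent regime)")
    2 * asin(wavelengthNm / (2 * pitchNm)) * 180 / pi
}

#' Snap a phase map to a meta-atom library
#'
#' Optional lookup replacing each continuous phase by the phase of the
#' nearest library meta-atom (by wrapped phase distance). The library is a
#' data frame with columns \code{diameter_nm}, \code{phase_rad},
#' \code{transmission}; no electromagnetic solver is involved.
#'
#' @param phase a \linkS4class{PhaseMap}.
#' @param library data frame of meta-atom entries.
#' @return a list with the quantized \linkS4class{PhaseMap} and the matrix
#'   of selected meta-atom diameters (nm; NA outside the aperture).
#' @export
snapToMetaAtoms <- function(phase, library) {
    stopifnot(is(phase, "PhaseMap"),
              all(c("diameter_nm", "phase_rad", "transmission") %in%
                  names(library)))
    libPhase <- library$phase_rad %% (2 * pi)
    ph <- phaseValues(phase)
    idx <- which(phase@aperture > 0)
    d <- outer(ph[idx], libPhase, function(a, b) {
        w <- abs(a - b) %% (2 * pi)
        pmin(w, 2 * pi - w)
    })
    pick <- max.col(-d)
    quant <- ph
    quant[idx] <- libPhase[pick]
    diam <- matrix(NA_real_, nrow(ph), ncol(ph))
    diam[idx] <- library$diameter_nm[pick]
    out <- phase
    out@phase <- quant
    list(phase = out, diametersNm = diam)
}
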