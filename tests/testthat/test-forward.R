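# Forward imaging operators for both detection paths.

smallStack <- function(n = 7L, q = 3L, px = 33L) {
    generatePatternStack(illuminationCodeFor(n),
                         layoutForFrame(n, q, px, px, 3L))
}

test_that("calibration stack realizes O x (pattern * PSF) exactly", {
    st <- smallStack()
    fr <- frames(st)
    # Identity limits.
    idd <- imageCalibrationStack(matrix(1, 33, 33), st, deltaKernel())
    expect_equal(frames(idd), fr, tolerance = 1e-12)
    zero <- imageCalibrationStack(matrix(0, 33, 33), st, gaussianPsf(0.54))
    expect_true(all(frames(zero) == 0))
    # Brute-force per-pixel oracle on a random object.
    set.seed(12)
    O <- matrix(runif(33 * 33), 33, 33)
    psf <- gaussianPsf(0.8)
    got <- frames(imageCalibrationStack(O, st, psf))
    for (k in c(1, 4, 7)) {
        oracle <- O * naiveConvolveSame(fr[, , k], kernelValues(psf))
        expect_equal(got[, , k], oracle, tolerance = 1e-10)
    }
    expect_error(imageCalibrationStack(matrix(1, 10, 10), st, psf),
                 "shape mismatch")
})

test_that("spectral calibration stack equals per-slice averaging by linearity", {
    st <- smallStack()
    cal <- imageCalibrationStack(matrix(1, 33, 33), st, gaussianPsf(0.54))
    sp <- spectralPsf(gaussianPsf(0.54), lengthPx = 6, angleDeg = -21,
                      channels = 5)
    avg <- averageSpectralPsf(sp)
    got <- frames(imageSpectralCalibrationStack(cal, avg))
    # Two-path computation: convolve with each slice, then average.
    kern <- kernelValues(sp)
    fr <- frames(cal)
    for (k in c(2, 6)) {
        acc <- matrix(0, 33, 33)
        for (c in 1:5)
            acc <- acc + naiveConvolveSame(fr[, , k], kern[, , c])
        expect_equal(got[, , k], acc / 5, tolerance = 1e-8)
    }
    # Delta kernel is the identity.
    expect_equal(frames(imageSpectralCalibrationStack(cal, deltaKernel())),
                 fr, tolerance = 1e-12)
    # Unit-sum kernel preserves total energy when the signal sits in the
    # interior (no leakage past the zero-padded border).
    O <- matrix(0, 33, 33); O[13:21, 13:21] <- 1
    inner <- imageCalibrationStack(O, st, deltaKernel())
    innerS <- imageSpectralCalibrationStack(inner, avg)
    expect_equal(sum(frames(innerS)[, , 2]), sum(frames(inner)[, , 2]),
                 tolerance = 1e-8)
})

test_that("tissue stack follows the scattering forward equation", {
    st <- smallStack()
    C <- 4L
    set.seed(5)
    cube <- array(runif(33 * 33 * C), c(33, 33, C))
    truth <- new("HyperCube", data = cube,
                 wavelengthsNm = seq(500, 650, length.out = C))
    psfI <- gaussianPsf(0.6)
    psfS <- gaussianPsf(1.4)
    got <- frames(imageTissueStack(truth, st, psfI, psfS))
    avgO <- apply(cube, c(1, 2), mean)
    fr <- frames(st)
    for (k in c(1, 5)) {
        ih <- naiveConvolveSame(fr[, , k], kernelValues(psfI))
        oracle <- naiveConvolveSame(avgO * ih, kernelValues(psfS))
        expect_equal(got[, , k], pmax(oracle, 0), tolerance = 1e-10)
    }
    # Transparent medium reduces to the calibration operator on Avg(O_H).
    noScat <- frames(imageTissueStack(truth, st, psfI, deltaKernel()))
    calEq <- frames(imageCalibrationStack(avgO, st, psfI))
    expect_equal(noScat, calEq, tolerance = 1e-12)
})

test_that("spectral tissue stack matches the brute-force channel loop", {
    st <- smallStack()
    C <- 5L
    sp <- spectralPsf(gaussianPsf(0.5), lengthPx = 5, angleDeg = -21,
                      channels = C)
    set.seed(6)
    cube <- array(runif(33 * 33 * C), c(33, 33, C))
    truth <- new("HyperCube", data = cube,
                 wavelengthsNm = seq(500, 650, length.out = C))
    psfI <- gaussianPsf(0.6)
    psfS <- gaussianPsf(1.1)
    got <- frames(imageTissueSpectralStack(truth, st, psfI, sp, psfS))
    fr <- frames(st)
    kern <- kernelValues(sp)
    for (k in c(3, 7)) {
        ih <- naiveConvolveSame(fr[, , k], kernelValues(psfI))
        acc <- matrix(0, 33, 33)
        for (c in seq_len(C))
            acc <- acc + naiveConvolveSame(cube[, , c] * ih, kern[, , c])
        oracle <- naiveConvolveSame(acc / C, kernelValues(psfS))
        expect_equal(got[, , k], pmax(oracle, 0), tolerance = 1e-10)
    }
})

test_that("single-channel delta dispersion reduces the spectral path to the normal path", {
    st <- smallStack()
    cube <- array(runif(33 * 33), c(33, 33, 1))
    truth <- new("HyperCube", data = cube, wavelengthsNm = 550)
    # One channel whose kernel is (numerically) a delta.
    sp <- spectralPsf(gaussianPsf(0.05), lengthPx = 0, angleDeg = 0,
                      channels = 1)
    a <- frames(imageTissueSpectralStack(truth, st, gaussianPsf(0.6), sp,
                                         gaussianPsf(1.0)))
    b <- frames(imageTissueStack(truth, st, gaussianPsf(0.6),
                                 gaussianPsf(1.0)))
    expect_equal(a, b, tolerance = 1e-3)
})

test_that("a point source with flat spectrum disperses into a tilted streak", {
    n <- 19L
    st <- generatePatternStack(illuminationCodeFor(n),
                               layoutForFrame(n, 5, 96, 96, 3))
    C <- 20L
    cube <- array(0, c(96, 96, C)); cube[48, 30, ] <- 1
    truth <- new("HyperCube", data = cube,
                 wavelengthsNm = seq(500, 650, length.out = C))
    sp <- spectralPsf(gaussianPsf(0.54), lengthPx = 30, angleDeg = -21,
                      channels = C)
    fs <- imageTissueSpectralStack(truth, st, deltaKernel(), sp,
                                   deltaKernel())
    # Sum over frames: every channel contributes somewhere in the cycle.
    img <- apply(frames(fs), c(1, 2), sum)
    on <- which(img > max(img) * 0.02, arr.ind = TRUE)
    spread <- sqrt((max(on[, 1]) - min(on[, 1]))^2 +
                   (max(on[, 2]) - min(on[, 2]))^2)
    expect_gt(spread, 25)          # approximately the dispersion length
    expect_lt(spread, 36)
    # Streak direction: regression slope of rows on columns matches -21 deg.
    slope <- unname(stats::coef(stats::lm(on[, 1] ~ on[, 2]))[2])
    fitAng <- atan2(-slope, 1) * 180 / pi
    expect_equal(fitAng, -21, tolerance = 4)
})

test_that("shot noise is unbiased and vanishes at high photon counts", {
    st <- smallStack()
    fs <- imageCalibrationStack(matrix(0.5, 33, 33), st, gaussianPsf(0.54))
    # Zero input stays zero.
    z <- addShotNoise(new("FrameStack", frames = array(0, c(4, 4, 2)),
                          path = "normal"), 100, seed = 1)
    expect_true(all(frames(z) == 0))
    # High photon budget: relative RMS error becomes negligible.
    hi <- addShotNoise(fs, 1e7, seed = 2)
    rel <- sqrt(mean((frames(hi) - frames(fs))^2)) / mean(frames(fs))
    expect_lt(rel, 1e-2)
    # Monte Carlo mean over seeds converges to the input within 4 SE.
    lam <- 50
    draws <- vapply(1:30, function(s)
        frames(addShotNoise(fs, lam, seed = s))[17, 17, 1], numeric(1))
    truthVal <- frames(fs)[17, 17, 1]
    se <- sqrt(truthVal / lam) / sqrt(30)
    expect_lt(abs(mean(draws) - truthVal), 4 * se)
    expect_error(addShotNoise(fs, 0), "positive")
})
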