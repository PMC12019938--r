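# Wide-field, sectioned and hyperspectral reconstruction.

test_that("wide-field imaging is the frame mean", {
    same <- new("FrameStack",
                frames = array(rep(matrix(1:16 / 16, 4, 4), 3), c(4, 4, 3)),
                path = "normal")
    expect_equal(widefield(same), matrix(1:16 / 16, 4, 4))
    # The Hadamard cycle averages to uniform illumination.
    wf <- widefield(fixture("stack19"))
    expect_true(all(abs(wf - 18 / 38) < 1e-15))
})

test_that("ideal sectioning is flat on pinholes and zero elsewhere", {
    n <- 19L
    code <- fixture("code19")
    stack <- generatePatternStack(code, assignCodes(n, 5L, n, n))
    fs <- imageCalibrationStack(matrix(1, n * 3, n * 3), stack,
                                deltaKernel())
    dec <- decodeStack(fs, code)
    mdp <- binarizePinholes(dec, code)
    ios <- opticalSection(fs, code, mdp, gridSigma = 0)
    img <- sectionedPixels(ios)
    # Every pixel belongs to exactly one pinhole slice; the decoded
    # self-value minus offset is (n+1)/4 = 5, averaged over n slices.
    expect_true(all(abs(img - 5 / n) < 1e-12))
})

test_that("no-scatter sectioning recovers the phantom at pinhole sites", {
    sc <- fixture("scene")
    ph <- makePhantom(sc$W, sc$H, seed = 21)
    spec <- dyeSpectra(sc$C)
    truth <- synthHyperspectral(ph, spec)
    fs <- imageTissueStack(truth, sc$stack, sc$psfImg, deltaKernel())
    ios <- opticalSection(fs, sc$code, sc$pinholes, gridSigma = 0)
    avgT <- apply(cubeData(truth), c(1, 2), mean)
    sites <- apply(maskArray(sc$pinholes), c(1, 2), max) > 0
    interior <- HadamardScope:::interiorMask(dim(avgT), 8L)
    sel <- sites & interior
    expect_gte(cor(sectionedPixels(ios)[sel], avgT[sel]), 0.99)
})

test_that("scattered background is suppressed by digital pinholing", {
    sc <- fixture("scene")
    ph <- makePhantom(sc$W, sc$H, seed = 21)
    truth <- synthHyperspectral(ph, dyeSpectra(sc$C))
    fs <- imageTissueStack(truth, sc$stack, sc$psfImg,
                           fixture("scatterKernel"))
    iwf <- widefield(fs)
    ios <- opticalSection(fs, sc$code, sc$pinholes, gridSigma = 3)
    rep <- compareToTruth(iwf, ios, NULL, truth)
    expect_lt(rep@backgroundSuppression, 1)
    expect_gt(rep@sectionedCor, 0.8)
})

test_that("spectral projection isolates a point source in a single slit", {
    sc <- fixture("scene")
    C <- sc$C
    # Source at a cell center (cell 22, 14 spans rows 64-66, cols 40-42),
    # so the imaging blur does not leak onto neighboring codes.
    cube <- array(0, c(sc$H, sc$W, C)); cube[65, 41, ] <- 1
    truth <- new("HyperCube", data = cube,
                 wavelengthsNm = seq(490, 700, length.out = C))
    fs <- imageTissueSpectralStack(truth, sc$stack, sc$psfImg, sc$psfSpec,
                                   deltaKernel())
    isp <- spectralProjection(fs, sc$code, sc$slits)
    vals <- decodedValues(isp)
    sliceEnergy <- apply(vals, 3, sum)
    # One slice (the source cell's code) carries nearly all signal.
    expect_gt(max(sliceEnergy) / sum(sliceEnergy), 0.9)
    k <- which.max(sliceEnergy)
    lab <- EBImage::bwlabel(vals[, , k] > max(vals) * 0.01)
    expect_equal(max(lab), 1)   # a single slit lights up
    # Delta dispersion reduces the projection to pinhole-masked sectioning.
    calDelta <- imageSpectralCalibrationStack(sc$calStack, deltaKernel())
    slitsDelta <- digitalSlits(calDelta, sc$code)
    fsN <- imageTissueStack(truth, sc$stack, sc$psfImg, deltaKernel())
    fsN@path <- "spectral"
    ispD <- spectralProjection(fsN, sc$code, slitsDelta)
    dec <- decodedValues(decodeStack(fsN, sc$code))
    off <- HadamardScope:::decodeOffsetImage(fsN, sc$n)
    oracle <- pmax(sweep(dec, c(1, 2), off), 0) * maskArray(sc$pinholes)
    expect_equal(decodedValues(ispD), oracle, tolerance = 1e-10)
})

test_that("hyperspectral round trip recovers point-source spectra", {
    sc <- fixture("scene")
    C <- sc$C
    spec <- dyeSpectra(C)
    Fm <- spectraMatrix(spec)
    cube <- array(0, c(sc$H, sc$W, C))
    cube[40, 40, ] <- Fm[1, ] * 100
    cube[80, 70, ] <- Fm[4, ] * 100
    truth <- new("HyperCube", data = cube, wavelengthsNm = wavelengths(spec))
    fs <- imageTissueSpectralStack(truth, sc$stack, sc$psfImg, sc$psfSpec,
                                   deltaKernel())
    isp <- spectralProjection(fs, sc$code, sc$slits)
    hy <- reconstructHyperspectral(isp, sc$pinholes, angleDeg = 21,
                                   channels = C, gridSigma = 0)
    hc <- cubeData(hy)
    s1 <- hc[40, 40, ]; s2 <- hc[80, 70, ]
    expect_gte(cosSim(s1, Fm[1, ]), 0.95)
    expect_gte(cosSim(s2, Fm[4, ]), 0.95)
    # Confusion: each source matches its own spectrum better than the other.
    expect_gt(cosSim(s1, Fm[1, ]), cosSim(s1, Fm[4, ]))
    expect_gt(cosSim(s2, Fm[4, ]), cosSim(s2, Fm[1, ]))
    # Zero projection gives a zero cube.
    z <- new("DecodedStack", values = decodedValues(isp) * 0,
             path = "spectral")
    expect_true(all(cubeData(reconstructHyperspectral(
        z, sc$pinholes, 21, C, 0)) == 0))
})

test_that("rotation round trip returns pinhole positions within a pixel", {
    sc <- fixture("scene")
    m <- maskArray(sc$pinholes)[, , 7]
    back <- rotateImage(rotateImage(m, 21, "nearest"), -21, "nearest")
    orig <- which(m > 0, arr.ind = TRUE)
    rec <- which(back > 0, arr.ind = TRUE)
    interior <- orig[, 1] > 20 & orig[, 1] < 108 & orig[, 2] > 20 &
        orig[, 2] < 108
    nearest <- vapply(which(interior), function(i) {
        min(sqrt((rec[, 1] - orig[i, 1])^2 + (rec[, 2] - orig[i, 2])^2))
    }, numeric(1))
    expect_lte(max(nearest), 1)
})

test_that("recovered spectral energy tracks sectioned intensity across pinholes", {
    sc <- fixture("scene")
    C <- sc$C
    # Flat-spectrum object with smooth spatial variation.
    base <- outer(seq(0.6, 1.4, length.out = sc$H),
                  seq(0.8, 1.2, length.out = sc$W))
    cube <- array(rep(base, C) / C, c(sc$H, sc$W, C))
    truth <- new("HyperCube", data = cube,
                 wavelengthsNm = seq(490, 700, length.out = C))
    fsN <- imageTissueStack(truth, sc$stack, sc$psfImg, deltaKernel())
    fsS <- imageTissueSpectralStack(truth, sc$stack, sc$psfImg, sc$psfSpec,
                                    deltaKernel())
    ios <- opticalSection(fsN, sc$code, sc$pinholes, gridSigma = 0)
    isp <- spectralProjection(fsS, sc$code, sc$slits)
    hy <- reconstructHyperspectral(isp, sc$pinholes, 21, C, gridSigma = 0)
    energy <- apply(cubeData(hy), c(1, 2), sum)
    sec <- sectionedPixels(ios)
    # Compare at pinhole-cell centers well inside the frame (profiles must
    # not exit the rotated frame).
    im <- indexMap(sc$stack)
    cells <- which(im > 0, arr.ind = TRUE)
    ctrR <- (cells[, 1] - 1) * 3 + 2
    ctrC <- (cells[, 2] - 1) * 3 + 2
    keep <- ctrR > 40 & ctrR < 88 & ctrC > 40 & ctrC < 68
    ratios <- energy[cbind(ctrR[keep], ctrC[keep])] /
        sec[cbind(ctrR[keep], ctrC[keep])]
    expect_lt((max(ratios) - min(ratios)) / stats::median(ratios), 0.1)
})

test_that("comparison metrics behave at the extremes", {
    sc <- fixture("scene")
    ph <- makePhantom(sc$W, sc$H, seed = 3)
    truth <- synthHyperspectral(ph, dyeSpectra(sc$C))
    avgT <- apply(cubeData(truth), c(1, 2), mean)
    perfect <- compareToTruth(avgT,
                              new("SectionedImage", image = avgT,
                                  gridSigma = 0), truth, truth)
    expect_equal(perfect@widefieldCor, 1)
    expect_equal(perfect@sectionedCor, 1)
    expect_true(all(abs(perfect@spectralCosines - 1) < 1e-9))
    zero <- compareToTruth(avgT * 0,
                           new("SectionedImage", image = avgT * 0,
                               gridSigma = 0), NULL, truth)
    expect_equal(zero@sectionedCor, 0)
    expect_true(is(zero, "MetricsReport"))
})
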