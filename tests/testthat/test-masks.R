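# Decoding and digital pinhole / slit mask construction.

test_that("decoding the ideal stack yields exactly the two code dot products", {
    for (cfg in list(c(3L, 1L), c(7L, 3L), c(11L, 3L), c(19L, 5L),
                     c(23L, 5L))) {
        n <- cfg[1]
        code <- illuminationCodeFor(n)
        stack <- generatePatternStack(code, assignCodes(n, cfg[2], n, n))
        vals <- decodedValues(decodeStack(stack, code))
        expect_identical(sort(unique(as.vector(vals))),
                         c((n - 3) / 4, (n - 1) / 2))
        # Self value appears exactly at the code's own cells.
        im <- indexMap(stack)
        cell <- patternLayout(stack)@cellPx
        for (r in c(1L, n)) {
            own <- vals[, , r] == (n - 1) / 2
            oracle <- (im[((seq_len(n * cell) - 1) %/% cell) + 1,
                          ((seq_len(n * cell) - 1) %/% cell) + 1] == r)
            expect_identical(own, oracle)
        }
    }
})

test_that("decoding an all-ones stack gives the column sum everywhere", {
    code <- fixture("code19")
    ones <- new("FrameStack", frames = array(1, c(6, 6, 19)),
                path = "normal")
    vals <- decodedValues(decodeStack(ones, code))
    expect_true(all(vals == 9))   # each code has (n-1)/2 = 9 on states
})

test_that("decoding is a linear temporal projection", {
    code <- fixture("code7")
    set.seed(8)
    s1 <- array(runif(6 * 6 * 7), c(6, 6, 7))
    s2 <- array(runif(6 * 6 * 7), c(6, 6, 7))
    f <- function(a) decodedValues(decodeStack(
        new("FrameStack", frames = a, path = "normal"), code))
    expect_equal(f(2 * s1 + 3 * s2), 2 * f(s1) + 3 * f(s2),
                 tolerance = 1e-12)
    # Brute-force projection oracle.
    P <- codeMatrix(code)
    got <- f(s1)
    for (r in c(1, 7)) {
        oracle <- matrix(0, 6, 6)
        for (k in 1:7) oracle <- oracle + s1[, , k] * P[k, r]
        expect_equal(got[, , r], oracle, tolerance = 1e-12)
    }
    expect_error(decodeStack(new("FrameStack",
                                 frames = array(1, c(4, 4, 6)),
                                 path = "normal"), code),
                 "frame-count mismatch")
})

test_that("ideal pinhole masks equal the index map and tile the frame", {
    for (n in c(7L, 19L)) {
        code <- illuminationCodeFor(n)
        stack <- generatePatternStack(code, assignCodes(n, 3L, n, n))
        dec <- decodeStack(stack, code)
        mask <- maskArray(binarizePinholes(dec, code))
        im <- indexMap(stack)
        cell <- 3L
        expand <- im[((seq_len(n * cell) - 1) %/% cell) + 1,
                     ((seq_len(n * cell) - 1) %/% cell) + 1]
        for (r in c(1L, n))
            expect_identical(mask[, , r] == 1, expand == r)
        # Partition property: slices disjoint, union covers every pixel.
        tot <- apply(mask, c(1, 2), sum)
        expect_true(all(tot == 1))
    }
})

test_that("binarization fails on signal-free decoded data", {
    code <- fixture("code7")
    flat <- new("DecodedStack", values = array(1, c(6, 6, 7)),
                path = "normal")
    expect_error(binarizePinholes(flat, code), "degenerate range")
})

test_that("blurred calibration yields one compact component per pinhole cell", {
    sc <- fixture("scene")
    mask <- maskArray(sc$pinholes)
    im <- indexMap(sc$stack)
    for (r in c(1L, 10L)) {
        lab <- EBImage::bwlabel(mask[, , r])
        nComp <- max(lab)
        expect_equal(nComp, sum(im == r))
        areas <- tabulate(lab[lab > 0])
        expect_true(all(areas <= sc$cell^2))
    }
})

test_that("Otsu thresholding gives a usable pinhole mask", {
    sc <- fixture("scene")
    m <- binarizePinholes(decodeStack(sc$calStack, sc$code), sc$code,
                          method = "otsu")
    expect_gt(sum(maskArray(m)), 0)
    # Pinhole slices still (near) disjoint after blurring.
    tot <- apply(maskArray(m), c(1, 2), sum)
    expect_lte(max(tot), 1)
})

componentAngle <- function(px) {
    x <- px[, 2]; y <- -px[, 1]
    cxy <- stats::cov(x, y)
    e <- eigen(matrix(c(stats::var(x), cxy, cxy, stats::var(y)), 2))
    a <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
    if (a > 90) a <- a - 180
    if (a <= -90) a <- a + 180
    a
}

test_that("digital slits contain their pinholes and tilt along the dispersion", {
    sc <- fixture("scene")
    pin <- maskArray(sc$pinholes)
    slit <- maskArray(sc$slits)
    # Every pinhole pixel is inside its slice's slit.
    expect_true(all(slit[pin == 1] == 1))
    # The mask as a whole is elongated at the dispersion angle: the
    # orientation of each labelled component (40 px slits chain into
    # diagonal runs at the default geometry) stays on the negative-tilt
    # side and the largest runs align with the chain direction.
    lab <- EBImage::bwlabel(slit[, , 4])
    big <- which(tabulate(lab[lab > 0]) > 200)
    angs <- vapply(big, function(i)
        componentAngle(which(lab == i, arr.ind = TRUE)), numeric(1))
    expect_true(all(angs < 0))
    # A normal-path stack is rejected.
    expect_error(digitalSlits(sc$calStack, sc$code), "spectral-path")
})

test_that("short slits are disjoint per slice and oriented at the dispersion angle", {
    # With a 10 px dispersion the nearest same-code slit (14.4 px ahead,
    # 4.1 px off the line) no longer chains, so each pinhole owns one
    # isolated slit.
    sc <- fixture("scene")
    spShort <- spectralPsf(sc$psfImg, lengthPx = 10, angleDeg = -21,
                           channels = 10)
    calSp <- imageSpectralCalibrationStack(sc$calStack,
                                           averageSpectralPsf(spShort))
    slits <- digitalSlits(calSp, sc$code, lengthPx = 10, angleDeg = -21)
    pin <- maskArray(sc$pinholes)
    m <- maskArray(slits)
    expect_true(all(m[pin == 1] == 1))
    for (r in c(4L, 12L)) {
        lab <- EBImage::bwlabel(m[, , r])
        # One component per pinhole cell: pairwise disjoint slits.
        expect_equal(max(lab), max(EBImage::bwlabel(pin[, , r])))
        sizes <- tabulate(lab[lab > 0])
        full <- which(sizes >= 0.9 * max(sizes))  # uncropped slits
        angs <- vapply(full, function(i)
            componentAngle(which(lab == i, arr.ind = TRUE)), numeric(1))
        # Short stubby components carry a few degrees of discretization
        # spread around the dispersion angle.
        expect_lt(max(abs(angs - (-21))), 6)
    }
})

test_that("delta dispersion collapses slits onto pinholes", {
    sc <- fixture("scene")
    calDelta <- imageSpectralCalibrationStack(sc$calStack, deltaKernel())
    slits <- digitalSlits(calDelta, sc$code)
    expect_identical(maskArray(slits), maskArray(sc$pinholes))
})
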