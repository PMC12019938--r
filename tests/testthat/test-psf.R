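# Imaging, scattering and spectral point spread functions.

test_that("Gaussian PSF is normalized with the exact discrete profile", {
    k <- gaussianPsf(0.54)
    v <- kernelValues(k)
    expect_lt(abs(sum(v) - 1), 1e-12)
    ctr <- (nrow(v) + 1) / 2
    # Midpoint discretization: 4-neighbor over center = exp(-1/(2 sigma^2)).
    expect_equal(v[ctr, ctr + 1] / v[ctr, ctr], exp(-1 / (2 * 0.54^2)),
                 tolerance = 1e-12)
    # Narrow sigma approaches a delta.
    tiny <- kernelValues(gaussianPsf(0.05))
    c2 <- (nrow(tiny) + 1) / 2
    expect_gte(tiny[c2, c2], 0.999)
    expect_error(gaussianPsf(0), "positive")
})

test_that("spectral PSF slices are translates along the dispersion angle", {
    base <- gaussianPsf(0.54)
    sp <- spectralPsf(base, lengthPx = 40, angleDeg = -21, channels = 40)
    kern <- kernelValues(sp)
    expect_true(all(abs(apply(kern, 3, sum) - 1) < 1e-6))
    # Centroid displacement between last and first slice: magnitude equals
    # the dispersion length, direction equals the dispersion angle.
    d <- kernelCentroid(kern[, , 40]) - kernelCentroid(kern[, , 1])
    expect_equal(sqrt(sum(d^2)), 40, tolerance = 1e-3)
    expect_equal(atan2(-d[["dRow"]], d[["dCol"]]) * 180 / pi, -21,
                 tolerance = 0.1)
    # Slice 1 is the unshifted base kernel.
    ctr <- (dim(kern)[1] + 1) %/% 2
    expect_equal(centerCrop(kern[, , 1], 2),
                 centerCrop(kernelValues(base), 2), tolerance = 1e-12)
    # Single channel: stack reduces to the base kernel.
    one <- kernelValues(spectralPsf(base, 40, -21, channels = 1))
    expect_equal(centerCrop(one[, , 1], 2), centerCrop(kernelValues(base), 2),
                 tolerance = 1e-12)
    expect_warning(spectralPsf(base, 10, -21, channels = 40), "sub-pixel")
})

test_that("spectral slices de-translate onto slice 1 within tolerance", {
    base <- gaussianPsf(0.54)
    # Integer 1 px spacing: exact translates (the 39 px / 40 channel ratio
    # trips the sub-pixel advisory, which is irrelevant here).
    spI <- suppressWarnings(
        spectralPsf(base, lengthPx = 39, angleDeg = 0, channels = 40))
    kI <- kernelValues(spI)
    for (c in c(10, 40)) {
        undone <- kI[, c(c:dim(kI)[2], seq_len(c - 1)), c]  # shift back
        expect_lt(max(abs(undone - kI[, , 1])), 1e-6)
    }
    # Fractional spacing at the default geometry: removing the integer part
    # of the displacement (an exact lattice shift) must leave slice 1
    # shifted by the fractional remainder only.
    spF <- spectralPsf(base, lengthPx = 40, angleDeg = -21, channels = 40)
    kF <- kernelValues(spF)
    supp <- dim(kF)[1]
    d <- spF@displacements[20, ]
    di <- floor(d)
    frac <- d - di
    undone <- HadamardScope:::shiftIntoSupport(
        kernelValues(base), supp, frac[["dRow"]], frac[["dCol"]])
    recent <- kF[, , 20]
    recent <- recent[c((di[["dRow"]] + 1):supp, seq_len(di[["dRow"]])),
                     c((di[["dCol"]] + 1):supp, seq_len(di[["dCol"]]))]
    expect_lt(max(abs(recent - undone)), 1e-9)
})

test_that("averaged spectral PSF is tilted at the dispersion angle", {
    sp <- spectralPsf(gaussianPsf(0.54), 40, -21, 40)
    avg <- averageSpectralPsf(sp)
    expect_lt(abs(sum(kernelValues(avg)) - 1), 1e-9)
    expect_equal(kernelOrientation(avg), -21, tolerance = 1)
    one <- spectralPsf(gaussianPsf(0.54), 40, -21, channels = 1)
    expect_equal(kernelValues(averageSpectralPsf(one)),
                 kernelValues(one)[, , 1], tolerance = 1e-12)
})

test_that("Monte Carlo free paths are exponential with mean 1/mus", {
    s <- sampleFreePaths(2e5, mus = 100, seed = 5)
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - 100), 3 * se)   # 100 um mean free path
})

test_that("scattering kernel is unit-sum, delta-like in the transparent limit", {
    k <- fixture("scatterKernel")
    v <- kernelValues(k)
    expect_true(all(v >= 0))
    expect_lt(abs(sum(v) - 1), 1e-9)
    # Transparent medium: depth far below the mean free path.
    kt <- monteCarloScatterPsf(scatterParams(mus = 0.5, photons = 5e4,
                                             seed = 1))
    vt <- kernelValues(kt)
    ctr <- (nrow(vt) + 1) / 2
    expect_gte(vt[ctr, ctr], 0.999)
})

test_that("scattering kernel is radially symmetric up to Monte Carlo noise", {
    k1 <- centerCrop(kernelValues(fixture("scatterKernel")), 60)
    k2 <- centerCrop(kernelValues(monteCarloScatterPsf(
        scatterParams(photons = 2e5, seed = 43))), 60)
    noise <- sqrt(mean((k1 - k2)^2))
    # Quadrant flips are symmetry operations of the expected kernel.
    flips <- list(k1[rev(seq_len(nrow(k1))), ],
                  k1[, rev(seq_len(ncol(k1)))], t(k1))
    for (f in flips)
        expect_lt(sqrt(mean((k1 - f)^2)), 3 * noise)
})

test_that("doubling the photon budget shrinks inter-seed differences ~ 1/sqrt(2)", {
    kern <- function(n, seed) centerCrop(kernelValues(
        monteCarloScatterPsf(scatterParams(photons = n, seed = seed))), 50)
    r1 <- sqrt(mean((kern(6e4, 11) - kern(6e4, 12))^2))
    r2 <- sqrt(mean((kern(1.2e5, 13) - kern(1.2e5, 14))^2))
    expect_gt(r2 / r1, 0.5)
    expect_lt(r2 / r1, 0.9)
})

test_that("pathological scattering parameters raise a zero-acceptance error", {
    # A vanishing collection cone accepts (almost surely) no photon.
    expect_error(
        monteCarloScatterPsf(scatterParams(na = 1e-9, photons = 1e4,
                                           seed = 1)),
        "zero acceptance")
    expect_error(scatterParams(photons = 100), "photons")
    expect_error(scatterParams(g = 1), "g must")
})
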