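# Run configuration and the end-to-end simulation pipeline.

#' Default run configuration
#'
#' All tunable parameters of the end-to-end simulation, with defaults set
#' to the study conditions: a 19-code (q = 5) illumination on 3-px cells,
#' 256 x 256 px frames, 40 spectral channels over 490-700 nm, a 0.54 px
#' imaging PSF, a Monte Carlo scattering PSF (100 cm^-1, 50 um depth,
#' NA 0.3, 1e6 photons) and a 40 px / -21 degree spectral dispersion.
#' Randomness flows from one master seed, split per stage.
#'
#' @param ... named overrides of any default entry.
#' @return a validated configuration list.
#' @export
defaultRunConfig <- function(...) {
    cfg <- list(
        n = 19L, q = 5L, cellPx = 3L,
        width = 256L, height = 256L,
        channels = 40L, bandNm = c(490, 700),
        sigmaImgPx = 0.54,
        scatter = list(mus = 100, mua = 0.1, g = 0.9, depthUm = 50,
                       na = 0.3, photons = 1e6, pixelUm = 0.65),
        dispersion = list(lengthPx = 40, angleDeg = -21.0),
        gridSigma = 3,
        speckleCount = 4L,
        hologram = list(enabled = TRUE, iterations = 100L,
                        diameterUm = 100, pitchNm = 330, wavelengthNm = 488,
                        targetPx = 342L),
        phantomStyle = "mixed",
        seed = 1L)
    over <- list(...)
    for (nm in names(over)) {
        if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
            cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
        else cfg[[nm]] <- over[[nm]]
    }
    validateRunConfig(cfg)
    cfg
}

#' Validate a run configuration
#'
#' Checks the Paley conditions on n, the layout parameter, that the
#' spectral dispersion fits the frame and that channel counts agree.
#' Called at load time by \code{\link{readRunConfig}} and by
#' \code{\link{runPipeline}}.
#'
#' @param cfg configuration list.
#' @return \code{cfg}, invisibly; stops with a stage-labelled error when
#'   invalid.
#' @export
validateRunConfig <- function(cfg) {
    n <- cfg$n
    if (!isPrime(n) || (n + 1L) %% 4L != 0L)
        stop("config: n = ", n, " violates the Paley conditions ",
             "(n prime, n + 1 divisible by 4)")
    if (cfg$q < 1L || cfg$q >= n)
        stop("config: q must satisfy 1 <= q < n")
    if (cfg$channels < 1L)
        stop("config: channels must be positive")
    if (cfg$dispersion$lengthPx >= min(cfg$width, cfg$height))
        stop("config: dispersion length does not fit inside the frame")
    if (cfg$channels > cfg$width)
        stop("config: more spectral channels than frame width")
    invisible(cfg)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg configuration list.
#' @param path YAML path.
#' @return \code{readRunConfig} returns the validated configuration.
#' @export
writeRunConfig <- function(cfg, path) {
    yaml::write_yaml(c(list(schema = "hadamardscope-config/1"), cfg), path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    cfg$schema <- NULL
    cfg <- utils::modifyList(defaultRunConfig(), cfg)
    for (nm in c("n", "q", "cellPx", "width", "height", "channels",
                 "speckleCount"))
        cfg[[nm]] <- as.integer(cfg[[nm]])
    validateRunConfig(cfg)
    cfg
}

stageSeed <- function(master, stage) {
    # Deterministic per-stage seeds, kept within the 32-bit integer range.
    as.integer((as.numeric(master) * 1009 + stage * 9973) %% 2147483647)
}

#' Run the end-to-end simulation pipeline
#'
#' Generates the phantom and dye spectra, builds the hyperspectral ground
#' truth, constructs the illumination code and pattern stack, designs the
#' hologram (optional), simulates calibration and tissue acquisitions in
#' both detection paths, derives the digital pinhole and slit masks, and
#' reconstructs the wide-field, optically sectioned and hyperspectral
#' images plus comparison metrics. Deterministic given the master seed.
#'
#' @param cfg configuration from \code{\link{defaultRunConfig}}.
#' @param outDir optional directory; when given, all artifacts are written
#'   (TIFF/CSV/JSON) together with a manifest of parameters and MD5 hashes.
#' @param verbose print stage progress.
#' @return a list bundle: phantom, spectra, truth, code, layout, stack,
#'   shift, psfs, hologram, masks, stacks, reconstructions and metrics.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir = NULL,
                        verbose = TRUE) {
    validateRunConfig(cfg)
    say <- function(...) if (verbose) message("[hadamardscope] ", ...)
    t0 <- Sys.time()

    say("stage codes: n = ", cfg$n, ", q = ", cfg$q)
    code <- illuminationCodeFor(cfg$n)
    layout <- layoutForFrame(cfg$n, cfg$q, cfg$width, cfg$height, cfg$cellPx)
    stack <- generatePatternStack(code, layout)
    shift <- selfSimilarityShift(stack)

    say("stage phantom: ", cfg$width, " x ", cfg$height, " px")
    phantom <- makePhantom(cfg$width, cfg$height,
                           seed = stageSeed(cfg$seed, 1L),
                           style = cfg$phantomStyle)
    spectra <- dyeSpectra(cfg$channels, cfg$bandNm)
    truth <- synthHyperspectral(phantom, spectra)

    say("stage psf: imaging sigma ", cfg$sigmaImgPx, " px; Monte Carlo ",
        cfg$scatter$photons, " photons")
    psfImg <- gaussianPsf(cfg$sigmaImgPx)
    sp <- cfg$scatter
    psfScatter <- monteCarloScatterPsf(scatterParams(
        mus = sp$mus, mua = sp$mua, g = sp$g, depthUm = sp$depthUm,
        na = sp$na, photons = sp$photons, pixelUm = sp$pixelUm,
        seed = stageSeed(cfg$seed, 2L)))
    psfSpec <- spectralPsf(psfImg, cfg$dispersion$lengthPx,
                           cfg$dispersion$angleDeg, cfg$channels)
    avgSpec <- averageSpectralPsf(psfSpec)

    hologram <- NULL
    if (isTRUE(cfg$hologram$enabled)) {
        say("stage hologram: GS ", cfg$hologram$iterations, " iterations")
        hp <- cfg$hologram
        period <- cfg$n * cfg$cellPx
        tgt <- hp$targetPx
        holoLayout <- layoutForFrame(cfg$n, cfg$q, tgt, tgt, cfg$cellPx)
        holoStack <- generatePatternStack(code, holoLayout)
        target <- frames(holoStack)[, , 1L]
        plan <- aperturePlan(hp$diameterUm, hp$pitchNm, hp$wavelengthNm)
        phase <- gerchbergSaxton(target, plan, hp$iterations,
                                 seed = stageSeed(cfg$seed, 3L))
        holo <- speckleAverage(phase, shiftPx = shift * cfg$n * cfg$cellPx,
                               count = cfg$speckleCount)
        hologram <- list(phase = phase, image = holo, target = target,
                         periodPx = period)
    }

    say("stage calibration: pinhole and slit masks")
    calObject <- matrix(1, cfg$height, cfg$width)
    calStack <- imageCalibrationStack(calObject, stack, psfImg)
    mdp <- binarizePinholes(decodeStack(calStack, code), code)
    calSpec <- imageSpectralCalibrationStack(calStack, avgSpec)
    mds <- digitalSlits(calSpec, code,
                        lengthPx = cfg$dispersion$lengthPx,
                        angleDeg = cfg$dispersion$angleDeg)

    say("stage forward: tissue acquisition, both paths")
    tissue <- imageTissueStack(truth, stack, psfImg, psfScatter)
    tissueSpec <- imageTissueSpectralStack(truth, stack, psfImg, psfSpec,
                                           psfScatter)
    if (!is.null(cfg$noisePhotonsPerUnit)) {
        tissue <- addShotNoise(tissue, cfg$noisePhotonsPerUnit,
                               stageSeed(cfg$seed, 4L))
        tissueSpec <- addShotNoise(tissueSpec, cfg$noisePhotonsPerUnit,
                                   stageSeed(cfg$seed, 5L))
    }

    say("stage reconstruction")
    iwf <- widefield(tissue)
    ios <- opticalSection(tissue, code, mdp, cfg$gridSigma)
    isp <- spectralProjection(tissueSpec, code, mds)
    ihyper <- reconstructHyperspectral(isp, mdp,
                                       angleDeg = -cfg$dispersion$angleDeg,
                                       channels = cfg$channels,
                                       gridSigma = cfg$gridSigma,
                                       wavelengthsNm = wavelengths(spectra))
    metrics <- compareToTruth(iwf, ios, ihyper, truth)
    say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

    bundle <- list(config = cfg, code = code, layout = layout, stack = stack,
                   shift = shift, phantom = phantom, spectra = spectra,
                   truth = truth, psfImg = psfImg, psfScatter = psfScatter,
                   psfSpectral = psfSpec, hologram = hologram,
                   pinholes = mdp, slits = mds, calibration = calStack,
                   tissue = tissue, tissueSpectral = tissueSpec,
                   widefield = iwf, sectioned = ios, projection = isp,
                   hyper = ihyper, metrics = metrics)
    if (!is.null(outDir)) writeBundle(bundle, outDir)
    bundle
}

# Write all pipeline artifacts and a manifest with parameter echoes and
# MD5 hashes, so two runs with the same seeds yield identical manifests.
writeBundle <- function(bundle, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    writePatternStack(bundle$stack, p("patterns.tif"), shift = bundle$shift)
    writeFloatTIFF(phantomImage(bundle$phantom), p("phantom.tif"))
    writeSpectraCSV(bundle$spectra, p("spectra.csv"))
    writeFloatTIFF(cubeData(bundle$truth), p("truth.tif"))
    writeFloatTIFF(kernelValues(bundle$psfScatter), p("psf_scatter.tif"))
    writeFloatTIFF(kernelValues(bundle$psfImg), p("psf_img.tif"))
    if (!is.null(bundle$hologram)) {
        writeFloatTIFF(phaseValues(bundle$hologram$phase),
                       p("hologram_phase.tif"))
        writeFloatTIFF(hologramIntensity(bundle$hologram$image),
                       p("hologram.tif"))
    }
    writeFloatTIFF(maskArray(bundle$pinholes), p("mask_pinholes.tif"))
    writeFloatTIFF(maskArray(bundle$slits), p("mask_slits.tif"))
    writeFloatTIFF(bundle$widefield, p("widefield.tif"))
    writeFloatTIFF(sectionedPixels(bundle$sectioned), p("sectioned.tif"))
    writeFloatTIFF(cubeData(bundle$hyper), p("hyper.tif"))
    writeMetricsJSON(bundle$metrics, p("metrics.json"))
    files <- sort(list.files(outDir, full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    hashes <- as.list(tools::md5sum(file.path(outDir, files)))
    names(hashes) <- files
    jsonlite::write_json(list(
        package = "HadamardScope",
        version = as.character(utils::packageVersion("HadamardScope")),
        config = bundle$config,
        shift = bundle$shift,
        files = hashes), p("manifest.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(outDir)
}
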