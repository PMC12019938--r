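# Generics and accessors. Slots are never read directly by user code.

#' Extract the frame array of a stack
#' @param x a \linkS4class{PatternStack} or \linkS4class{FrameStack}.
#' @return numeric array (h x w x n).
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "PatternStack", function(x) x@frames)

#' @rdname frames
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' Extract the binary code matrix P
#' @param x an \linkS4class{IlluminationCode} or \linkS4class{PatternStack}.
#' @return integer 0/1 matrix.
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))

#' @rdname codeMatrix
#' @export
setMethod("codeMatrix", "IlluminationCode", function(x) x@P)

#' @rdname codeMatrix
#' @export
setMethod("codeMatrix", "PatternStack", function(x) x@code@P)

#' Code length n (or Hadamard order for a HadamardMatrix)
#' @param x a code-bearing object.
#' @return integer.
#' @export
setGeneric("codeOrder", function(x) standardGeneric("codeOrder"))

#' @rdname codeOrder
#' @export
setMethod("codeOrder", "HadamardMatrix", function(x) x@order)

#' @rdname codeOrder
#' @export
setMethod("codeOrder", "IlluminationCode", function(x) x@n)

#' @rdname codeOrder
#' @export
setMethod("codeOrder", "PatternStack", function(x) x@code@n)

#' @rdname codeOrder
#' @export
setMethod("codeOrder", "PatternLayout", function(x) x@n)

#' Hadamard matrix entries
#' @param x a \linkS4class{HadamardMatrix}.
#' @return integer +1/-1 matrix.
#' @export
setGeneric("hadamardEntries", function(x) standardGeneric("hadamardEntries"))

#' @rdname hadamardEntries
#' @export
setMethod("hadamardEntries", "HadamardMatrix", function(x) x@entries)

#' Cell-to-code index map of a layout
#' @param x a \linkS4class{PatternLayout} or \linkS4class{PatternStack}.
#' @return integer matrix (cellsHigh x cellsWide) of 1-based code indices.
#' @export
setGeneric("indexMap", function(x) standardGeneric("indexMap"))

#' @rdname indexMap
#' @export
setMethod("indexMap", "PatternLayout", function(x) x@indexMap)

#' @rdname indexMap
#' @export
setMethod("indexMap", "PatternStack", function(x) x@layout@indexMap)

#' Layout of a pattern stack
#' @param x a \linkS4class{PatternStack}.
#' @return the \linkS4class{PatternLayout}.
#' @export
setGeneric("patternLayout", function(x) standardGeneric("patternLayout"))

#' @rdname patternLayout
#' @export
setMethod("patternLayout", "PatternStack", function(x) x@layout)

#' Illumination code of a pattern stack
#' @param x a \linkS4class{PatternStack}.
#' @return the \linkS4class{IlluminationCode}.
#' @export
setGeneric("illuminationCode",
           function(x) standardGeneric("illuminationCode"))

#' @rdname illuminationCode
#' @export
setMethod("illuminationCode", "PatternStack", function(x) x@code)

#' Kernel values of a PSF
#' @param x a \linkS4class{Kernel2D} or \linkS4class{SpectralKernelStack}.
#' @return numeric matrix, or array for a spectral stack.
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname kernelValues
#' @export
setMethod("kernelValues", "Kernel2D", function(x) x@values)

#' @rdname kernelValues
#' @export
setMethod("kernelValues", "SpectralKernelStack", function(x) x@kernels)

#' Decoded value array
#' @param x a \linkS4class{DecodedStack}.
#' @return numeric array (h x w x n).
#' @export
setGeneric("decodedValues", function(x) standardGeneric("decodedValues"))

#' @rdname decodedValues
#' @export
setMethod("decodedValues", "DecodedStack", function(x) x@values)

#' Binary mask array
#' @param x a \linkS4class{PinholeMask} or \linkS4class{SlitMask}.
#' @return binary array (h x w x n).
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname maskArray
#' @export
setMethod("maskArray", "PinholeMask", function(x) x@mask)

#' @rdname maskArray
#' @export
setMethod("maskArray", "SlitMask", function(x) x@mask)

#' Hyperspectral cube data
#' @param x a \linkS4class{HyperCube}.
#' @return numeric array (h x w x C).
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname cubeData
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' Wavelength axis
#' @param x a \linkS4class{HyperCube} or \linkS4class{EmissionSpectra}.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengthsNm)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "EmissionSpectra", function(x) x@wavelengthsNm)

#' Emission spectra matrix
#' @param x an \linkS4class{EmissionSpectra}.
#' @return numeric matrix (dyes x channels), rows unit-sum.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "EmissionSpectra", function(x) x@spectra)

#' Phantom image array
#' @param x a \linkS4class{MultiChannelPhantom}.
#' @return numeric array (h x w x 4).
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname phantomImage
#' @export
setMethod("phantomImage", "MultiChannelPhantom", function(x) x@image)

#' Phase values of a hologram design
#' @param x a \linkS4class{PhaseMap}.
#' @return numeric matrix of phases in radians.
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))

#' @rdname phaseValues
#' @export
setMethod("phaseValues", "PhaseMap", function(x) x@phase)

#' Per-iteration Fourier-magnitude RMS errors of a phase retrieval run
#' @param x a \linkS4class{PhaseMap}.
#' @return numeric vector, one value per iteration.
#' @export
setGeneric("iterationErrors", function(x) standardGeneric("iterationErrors"))

#' @rdname iterationErrors
#' @export
setMethod("iterationErrors", "PhaseMap", function(x) x@errors)

#' Far-field intensity of a hologram
#' @param x a \linkS4class{HologramImage}.
#' @return non-negative numeric matrix.
#' @export
setGeneric("hologramIntensity",
           function(x) standardGeneric("hologramIntensity"))

#' @rdname hologramIntensity
#' @export
setMethod("hologramIntensity", "HologramImage", function(x) x@intensity)

#' Sectioned image pixels
#' @param x a \linkS4class{SectionedImage}.
#' @return non-negative numeric matrix.
#' @export
setGeneric("sectionedPixels", function(x) standardGeneric("sectionedPixels"))

#' @rdname sectionedPixels
#' @export
setMethod("sectionedPixels", "SectionedImage", function(x) x@image)

# ---- show methods ----------------------------------------------------------

setMethod("show", "HadamardMatrix", function(object) {
    cat("HadamardMatrix of order", object@order,
        sprintf("(n = %d)\n", object@order - 1L))
})

setMethod("show", "IlluminationCode", function(object) {
    n <- object@n
    cat(sprintf("IlluminationCode: n = %d, self-dot = %d, cross-dot = %d\n",
                n, (n - 1L) / 2L, (n - 3L) / 4L))
})

setMethod("show", "PatternLayout", function(object) {
    cat(sprintf(
        "PatternLayout: n = %d, q = %d, cell = %d px, %d x %d px (%d x %d cells)\n",
        object@n, object@q, object@cellPx, object@widthPx, object@heightPx,
        object@cellsWide, object@cellsHigh))
})

setMethod("show", "PatternStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("PatternStack: %d frames of %d x %d px (n = %d, q = %d)\n",
                d[3L], d[2L], d[1L], object@code@n, object@layout@q))
})

setMethod("show", "Kernel2D", function(object) {
    cat(sprintf("Kernel2D: %d x %d, unit energy\n",
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "SpectralKernelStack", function(object) {
    d <- dim(object@kernels)
    cat(sprintf(
        "SpectralKernelStack: %d channels, dispersion %.1f px at %.1f deg\n",
        d[3L], object@lengthPx, object@angleDeg))
})

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("FrameStack (%s path): %d frames of %d x %d px\n",
                object@path, d[3L], d[2L], d[1L]))
})

setMethod("show", "DecodedStack", function(object) {
    d <- dim(object@values)
    cat(sprintf("DecodedStack (%s path): %d slices of %d x %d px\n",
                object@path, d[3L], d[2L], d[1L]))
})

setMethod("show", "PinholeMask", function(object) {
    d <- dim(object@mask)
    cat(sprintf("PinholeMask: %d slices, %d marked px (offset %.2f)\n",
                d[3L], sum(object@mask), object@offsetValue))
})

setMethod("show", "SlitMask", function(object) {
    d <- dim(object@mask)
    cat(sprintf(
        "SlitMask: %d slices, %d marked px, %.0f px slits at %.1f deg\n",
        d[3L], sum(object@mask), object@lengthPx, object@angleDeg))
})

setMethod("show", "MultiChannelPhantom", function(object) {
    d <- dim(object@image)
    cat(sprintf("MultiChannelPhantom: %d x %d px, channels: %s\n",
                d[2L], d[1L], paste(object@labels, collapse = ", ")))
})

setMethod("show", "EmissionSpectra", function(object) {
    cat(sprintf("EmissionSpectra: %d dyes x %d channels (%.0f-%.0f nm)\n",
                nrow(object@spectra), ncol(object@spectra),
                min(object@wavelengthsNm), max(object@wavelengthsNm)))
})

setMethod("show", "HyperCube", function(object) {
    d <- dim(object@data)
    cat(sprintf("HyperCube: %d x %d px, %d channels (%.0f-%.0f nm)\n",
                d[2L], d[1L], d[3L], min(object@wavelengthsNm),
                max(object@wavelengthsNm)))
})

setMethod("show", "PhaseMap", function(object) {
    cat(sprintf(
        "PhaseMap: %d x %d grid, %d aperture px, %d GS iterations (final err %.4g)\n",
        nrow(object@phase), ncol(object@phase), sum(object@aperture),
        length(object@errors), object@errors[length(object@errors)]))
})

setMethod("show", "HologramImage", function(object) {
    cat(sprintf("HologramImage: %d x %d, total intensity %.4g\n",
                nrow(object@intensity), ncol(object@intensity),
                sum(object@intensity)))
})

setMethod("show", "SectionedImage", function(object) {
    cat(sprintf("SectionedImage: %d x %d px (grid filter sigma %.2f px)\n",
                ncol(object@image), nrow(object@image), object@gridSigma))
})

setMethod("show", "MetricsReport", function(object) {
    cat("MetricsReport\n")
    cat(sprintf("  wide-field correlation : %.4f\n", object@widefieldCor))
    cat(sprintf("  sectioned correlation  : %.4f\n", object@sectionedCor))
    if (length(object@spectralCosines))
        cat(sprintf("  spectral cosine (mean) : %.4f over %d pinholes\n",
                    mean(object@spectralCosines),
                    length(object@spectralCosines)))
    cat(sprintf("  background suppression : %.4f\n",
                object@backgroundSuppression))
})

setMethod("show", "ScatterParams", function(object) {
    cat(sprintf(
        "ScatterParams: mus %.0f/cm, mua %.2f/cm, g %.2f, depth %.0f um, NA %.2f, %g photons\n",
        object@mus, object@mua, object@g, object@depthUm, object@na,
        object@photons))
})
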