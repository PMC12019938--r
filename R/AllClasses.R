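# S4 classes for the coded-illumination microscopy toolkit.

#' HadamardMatrix: a Paley-type Hadamard matrix
#'
#' An order-\eqn{m} matrix with entries in \{-1, +1\} whose rows are mutually
#' orthogonal, \eqn{H H^T = m I}. Built by \code{\link{paleyHadamard}} from
#' quadratic residues modulo the prime \eqn{n = m - 1}, with an all-ones
#' border row and column.
#'
#' @slot order integer, the order \eqn{m} (divisible by 4, \eqn{m-1} prime).
#' @slot entries integer matrix of +1/-1 values.
#' @export
setClass("HadamardMatrix",
    representation(order = "integer", entries = "matrix"),
    validity = function(object) {
        m <- object@order
        H <- object@entries
        if (!all(dim(H) == m))
            return("entries must be an order x order matrix")
        if (!all(H %in% c(-1L, 1L)))
            return("entries must be +1/-1")
        if (m %% 4L != 0L)
            return("order must be divisible by 4")
        if (!isPrime(m - 1L))
            return("order - 1 must be prime")
        G <- H %*% t(H)
        if (!all(G == m * diag(m)))
            return("H %*% t(H) != m * I: rows are not orthogonal")
        TRUE
    })

#' IlluminationCode: the binary \{0,1\} modified Hadamard code
#'
#' The \eqn{n \times n} symmetric binary matrix \eqn{P} obtained by dropping
#' the all-ones border of an order-\eqn{m} Hadamard matrix (\eqn{n = m - 1})
#' and mapping \eqn{\pm 1 \to \{1, 0\}} via \eqn{(x+1)/2}. Column dot
#' products are \eqn{(n-1)/2} with itself and \eqn{(n-3)/4} across columns.
#'
#' @slot n integer code length (prime, \eqn{n + 1} divisible by 4).
#' @slot P integer matrix of 0/1 values.
#' @export
setClass("IlluminationCode",
    representation(n = "integer", P = "matrix"),
    validity = function(object) {
        n <- object@n
        P <- object@P
        if (!all(dim(P) == n)) return("P must be n x n")
        if (!all(P %in% c(0L, 1L))) return("P must be binary")
        if (!all(P == t(P))) return("P must be symmetric")
        if (!all(colSums(P) == (n - 1L) / 2L))
            return("each column must have (n-1)/2 ones")
        G <- crossprod(P)
        selfDot <- (n - 1L) / 2L
        crossDot <- (n - 3L) / 4L
        want <- matrix(crossDot, n, n); diag(want) <- selfDot
        if (!all(G == want))
            return("column dot products violate the (n-1)/2 / (n-3)/4 identities")
        TRUE
    })

#' PatternLayout: spatial assignment of code indices to cells
#'
#' Each illumination cell at 0-based coordinates \eqn{(i, j)} (row, column)
#' carries code index \eqn{k(i,j) = ((i q + j) \bmod n) + 1}; cells are
#' upsampled to \code{cellPx} camera pixels per edge.
#'
#' @slot n integer code length.
#' @slot q integer layout parameter, \eqn{1 \le q < n}.
#' @slot cellPx integer cell edge in pixels.
#' @slot cellsWide,cellsHigh integer cell-lattice dimensions.
#' @slot widthPx,heightPx integer pixel dimensions (lattice cropped at the
#'   right/bottom edges when not multiples of \code{cellPx}).
#' @slot indexMap integer matrix (cellsHigh x cellsWide) of code indices.
#' @slot verticalSpacing integer, the rule-of-thumb vertical pinhole spacing
#'   \code{round(n / q)} in cells.
#' @export
setClass("PatternLayout",
    representation(n = "integer", q = "integer", cellPx = "integer",
                   cellsWide = "integer", cellsHigh = "integer",
                   widthPx = "integer", heightPx = "integer",
                   indexMap = "matrix", verticalSpacing = "integer"),
    validity = function(object) {
        n <- object@n; q <- object@q
        if (q < 1L || q >= n) return("q must satisfy 1 <= q < n")
        im <- object@indexMap
        if (!all(dim(im) == c(object@cellsHigh, object@cellsWide)))
            return("indexMap dimensions must match the cell lattice")
        i <- matrix(seq_len(object@cellsHigh) - 1L, object@cellsHigh,
                    object@cellsWide)
        j <- matrix(seq_len(object@cellsWide) - 1L, object@cellsHigh,
                    object@cellsWide, byrow = TRUE)
        if (!all(im == ((i * q + j) %% n) + 1L))
            return("indexMap does not follow k(i,j) = mod(i*q + j, n) + 1")
        TRUE
    })

#' PatternStack: the n binary illumination frames
#'
#' @slot frames binary numeric array (heightPx x widthPx x n); frame k is on
#'   at pixels of cell (i, j) iff \code{P[indexMap(i,j), k] == 1}.
#' @slot layout a \linkS4class{PatternLayout}.
#' @slot code an \linkS4class{IlluminationCode}.
#' @export
setClass("PatternStack",
    representation(frames = "array", layout = "PatternLayout",
                   code = "IlluminationCode"),
    validity = function(object) {
        d <- dim(object@frames)
        if (length(d) != 3L) return("frames must be a 3D array")
        if (d[3L] != object@code@n) return("frame count must equal n")
        if (d[1L] != object@layout@heightPx || d[2L] != object@layout@widthPx)
            return("frame dimensions must match the layout")
        if (!all(object@frames %in% c(0, 1))) return("frames must be binary")
        TRUE
    })

#' Kernel2D: a normalized point spread function
#'
#' Odd-sized square non-negative kernel summing to one, centered at its
#' middle element.
#'
#' @slot values numeric matrix.
#' @export
setClass("Kernel2D",
    representation(values = "matrix"),
    validity = function(object) {
        v <- object@values
        if (nrow(v) != ncol(v)) return("kernel must be square")
        if (nrow(v) %% 2L == 0L) return("kernel size must be odd")
        if (any(v < 0)) return("kernel must be non-negative")
        if (abs(sum(v) - 1) > 1e-8) return("kernel must sum to 1")
        TRUE
    })

#' SpectralKernelStack: wavelength-indexed translated PSF copies
#'
#' Slice \eqn{c} is the base imaging kernel translated by
#' \eqn{(c-1)/(C-1)} of the dispersion length along the dispersion angle
#' (counter-clockwise positive from the +x/column axis); slice 1 is
#' unshifted.
#'
#' @slot kernels numeric array (support x support x channels); every slice
#'   sums to 1.
#' @slot lengthPx maximum dispersion length in pixels.
#' @slot angleDeg dispersion angle in degrees.
#' @slot displacements channels x 2 matrix of (dCol, dRow) pixel offsets.
#' @export
setClass("SpectralKernelStack",
    representation(kernels = "array", lengthPx = "numeric",
                   angleDeg = "numeric", displacements = "matrix"),
    validity = function(object) {
        d <- dim(object@kernels)
        if (length(d) != 3L) return("kernels must be a 3D array")
        if (d[1L] != d[2L]) return("kernel support must be square")
        if (any(object@kernels < 0)) return("kernels must be non-negative")
        s <- apply(object@kernels, 3L, sum)
        if (any(abs(s - 1) > 1e-6)) return("every slice must sum to 1")
        if (nrow(object@displacements) != d[3L])
            return("one displacement per channel required")
        TRUE
    })

#' ScatterParams: Monte Carlo tissue-scattering parameters
#'
#' @slot mus scattering coefficient, cm^-1.
#' @slot mua absorption coefficient, cm^-1.
#' @slot g Henyey-Greenstein anisotropy, \eqn{0 \le g < 1}.
#' @slot depthUm emitter depth below the surface, micrometers.
#' @slot na numerical aperture of the collection cone.
#' @slot lambdaExNm,lambdaEmNm excitation/emission wavelengths, nm.
#' @slot photons photon budget.
#' @slot pixelUm detector pixel size at the sample, micrometers.
#' @slot seed RNG seed.
#' @export
setClass("ScatterParams",
    representation(mus = "numeric", mua = "numeric", g = "numeric",
                   depthUm = "numeric", na = "numeric",
                   lambdaExNm = "numeric", lambdaEmNm = "numeric",
                   photons = "numeric", pixelUm = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (object@mus <= 0) return("mus must be positive")
        if (object@mua < 0) return("mua must be non-negative")
        if (object@g < 0 || object@g >= 1) return("g must be in [0, 1)")
        if (object@photons < 1e4) return("photons must be >= 1e4")
        if (object@na <= 0 || object@na > 1) return("na must be in (0, 1]")
        if (object@depthUm <= 0) return("depthUm must be positive")
        if (object@pixelUm <= 0) return("pixelUm must be positive")
        TRUE
    })

#' AperturePlan: metasurface aperture geometry
#'
#' @slot diameterUm metasurface diameter in micrometers.
#' @slot pitchNm meta-atom pitch in nanometers.
#' @slot wavelengthNm design wavelength in nanometers.
#' @slot atomsPerSide integer, \code{floor(diameter / pitch)}.
#' @export
setClass("AperturePlan",
    representation(diameterUm = "numeric", pitchNm = "numeric",
                   wavelengthNm = "numeric", atomsPerSide = "integer"),
    validity = function(object) {
        want <- as.integer(floor(object@diameterUm * 1e3 / object@pitchNm))
        if (object@atomsPerSide != want)
            return("atomsPerSide must equal floor(diameter / pitch)")
        TRUE
    })

#' PhaseMap: phase-only hologram design
#'
#' @slot phase per-pixel phase in [0, 2*pi), defined inside the aperture.
#' @slot aperture logical matrix marking the circular aperture.
#' @slot target the binary target pattern the phases were optimized for.
#' @slot plan an \linkS4class{AperturePlan}.
#' @slot errors Fourier-magnitude RMS error per iteration (non-increasing).
#' @slot seed RNG seed used for phase initialization.
#' @export
setClass("PhaseMap",
    representation(phase = "matrix", aperture = "matrix", target = "matrix",
                   plan = "AperturePlan", errors = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (!all(dim(object@phase) == dim(object@aperture)))
            return("phase and aperture dimensions must agree")
        ph <- object@phase[object@aperture > 0]
        if (any(ph < 0 | ph >= 2 * pi + 1e-12))
            return("phase must lie in [0, 2*pi)")
        TRUE
    })

#' HologramImage: simulated far-field intensity
#'
#' @slot intensity non-negative far-field intensity grid.
#' @slot apertureEnergy total field energy in the aperture plane (equals
#'   the total far-field intensity under the unitary transform).
#' @export
setClass("HologramImage",
    representation(intensity = "matrix", apertureEnergy = "numeric"),
    validity = function(object) {
        if (any(object@intensity < -1e-12))
            return("intensity must be non-negative")
        TRUE
    })

#' FrameStack: simulated camera frames under sequential illumination
#'
#' @slot frames numeric array (h x w x n), non-negative.
#' @slot path detection path tag, \code{"normal"} or \code{"spectral"}.
#' @export
setClass("FrameStack",
    representation(frames = "array", path = "character"),
    validity = function(object) {
        if (length(dim(object@frames)) != 3L)
            return("frames must be a 3D array")
        if (!object@path %in% c("normal", "spectral"))
            return("path must be 'normal' or 'spectral'")
        if (any(object@frames < -1e-9))
            return("frames must be non-negative")
        TRUE
    })

#' DecodedStack: temporal Hadamard projections of a frame stack
#'
#' Slice \eqn{r} holds the per-pixel projection of the temporal signal onto
#' column \eqn{r} of the code.
#'
#' @slot values numeric array (h x w x n).
#' @slot path source detection path tag.
#' @export
setClass("DecodedStack",
    representation(values = "array", path = "character"),
    validity = function(object) {
        if (length(dim(object@values)) != 3L)
            return("values must be a 3D array")
        TRUE
    })

#' PinholeMask: binary digital pinhole array
#'
#' @slot mask binary array (h x w x n); slice r marks the pinholes of code r.
#' @slot offsetValue the cross-talk offset (n-3)/4 subtracted before
#'   thresholding.
#' @slot thresholdFraction the threshold applied to the range-normalized
#'   decoded values.
#' @export
setClass("PinholeMask",
    representation(mask = "array", offsetValue = "numeric",
                   thresholdFraction = "numeric"),
    validity = function(object) {
        if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
        TRUE
    })

#' SlitMask: binary digital slit array
#'
#' The pinhole footprint extended along the spectral dispersion direction.
#'
#' @slot mask binary array (h x w x n).
#' @slot offsetValue cross-talk offset subtracted before thresholding.
#' @slot thresholdFraction threshold on the max-normalized decoded values.
#' @slot lengthPx nominal slit (dispersion) length in pixels.
#' @slot angleDeg dispersion angle in degrees.
#' @export
setClass("SlitMask",
    representation(mask = "array", offsetValue = "numeric",
                   thresholdFraction = "numeric", lengthPx = "numeric",
                   angleDeg = "numeric"),
    validity = function(object) {
        if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
        TRUE
    })

#' MultiChannelPhantom: synthetic 4-channel fluorescence image
#'
#' Stand-in for a multi-stained tissue image: nucleus-like disks,
#' curvilinear filaments and ramified blobs.
#'
#' @slot image non-negative numeric array (h x w x 4).
#' @slot labels channel labels.
#' @export
setClass("MultiChannelPhantom",
    representation(image = "array", labels = "character"),
    validity = function(object) {
        d <- dim(object@image)
        if (length(d) != 3L || d[3L] != 4L)
            return("image must be h x w x 4")
        if (any(!is.finite(object@image)) || any(object@image < 0))
            return("image must be finite and non-negative")
        TRUE
    })

#' EmissionSpectra: dye emission spectra
#'
#' @slot spectra numeric matrix (dyes x channels), each row unit-sum.
#' @slot wavelengthsNm strictly increasing wavelength axis, nm.
#' @export
setClass("EmissionSpectra",
    representation(spectra = "matrix", wavelengthsNm = "numeric"),
    validity = function(object) {
        if (ncol(object@spectra) != length(object@wavelengthsNm))
            return("wavelength axis must match spectra columns")
        if (any(object@spectra < 0)) return("spectra must be non-negative")
        if (any(abs(rowSums(object@spectra) - 1) > 1e-8))
            return("each spectrum must be normalized to unit sum")
        if (any(diff(object@wavelengthsNm) <= 0))
            return("wavelengths must be strictly increasing")
        TRUE
    })

#' HyperCube: hyperspectral image cube
#'
#' Used both for the synthetic ground truth \eqn{O_H = I_R \circ F} and for
#' reconstructed hyperspectral images.
#'
#' @slot data numeric array (h x w x C), non-negative.
#' @slot wavelengthsNm wavelength axis of length C.
#' @export
setClass("HyperCube",
    representation(data = "array", wavelengthsNm = "numeric"),
    validity = function(object) {
        d <- dim(object@data)
        if (length(d) != 3L) return("data must be a 3D array")
        if (length(object@wavelengthsNm) != d[3L])
            return("wavelength axis must match the channel dimension")
        if (any(object@data < -1e-9)) return("data must be non-negative")
        TRUE
    })

#' SectionedImage: optically sectioned reconstruction
#'
#' @slot image non-negative matrix.
#' @slot gridSigma sigma (pixels) of the Gaussian grid-artifact filter used.
#' @export
setClass("SectionedImage",
    representation(image = "matrix", gridSigma = "numeric"),
    validity = function(object) {
        if (any(object@image < -1e-9)) return("image must be non-negative")
        TRUE
    })

#' MetricsReport: reconstruction quality summary
#'
#' @slot widefieldCor Pearson correlation of the wide-field image with the
#'   channel-averaged ground truth.
#' @slot sectionedCor same for the optically sectioned image.
#' @slot spectralCosines cosine similarities between recovered and true
#'   spectra at sampled pinhole pixels.
#' @slot backgroundSuppression normalized background energy of the sectioned
#'   image divided by that of the wide-field image (< 1 means suppression).
#' @export
setClass("MetricsReport",
    representation(widefieldCor = "numeric", sectionedCor = "numeric",
                   spectralCosines = "numeric",
                   backgroundSuppression = "numeric"),
    validity = function(object) {
        cs <- object@spectralCosines
        if (length(cs) && any(cs < -1 - 1e-9 | cs > 1 + 1e-9))
            return("similarities must lie in [-1, 1]")
        TRUE
    })
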