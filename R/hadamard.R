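# Paley-type Hadamard codes, spatial layout, pattern stacks, self-similarity.

#' Construct a Paley-type Hadamard matrix
#'
#' Builds an order-\eqn{m} Hadamard matrix from the quadratic residues of the
#' prime \eqn{n = m - 1} (\eqn{n \equiv 3 \bmod 4}). The first row and column
#' are all +1; the core entry at 0-based \eqn{(a, b)} is +1 when
#' \eqn{(a + b) \bmod n} is a non-zero quadratic residue and -1 otherwise.
#' This reflected quadratic-residue core is row-permutation-equivalent to the
#' classical circulant construction, but makes the core -- and hence the
#' derived \{0,1\} code of \code{\link{modifiedMatrix}} -- symmetric, while
#' retaining the cyclic column structure that gives the illumination patterns
#' their self-similarity.
#'
#' @param m Hadamard order; must be divisible by 4 with \eqn{m - 1} prime.
#' @return a \linkS4class{HadamardMatrix} satisfying \eqn{H H^T = m I}
#'   exactly (integer arithmetic).
#' @examples
#' H <- paleyHadamard(20)
#' all(hadamardEntries(H) %*% t(hadamardEntries(H)) == 20 * diag(20))
#' @seealso \code{\link{validOrders}}, \code{\link{modifiedMatrix}}
#' @export
paleyHadamard <- function(m) {
    m <- as.integer(m)
    if (m %% 4L != 0L)
        stop("invalid order: m = ", m, " is not divisible by 4")
    n <- m - 1L
    if (!isPrime(n))
        stop("invalid order: m - 1 = ", n, " is not prime")
    # Quadratic residues modulo n.
    qr <- rep(FALSE, n)                      # index = residue + 1
    qr[(seq_len((n - 1L) / 2L)^2 %% n) + 1L] <- TRUE
    a <- matrix(0L:(n - 1L), n, n)
    core <- matrix(ifelse(qr[((a + t(a)) %% n) + 1L], 1L, -1L), n, n)
    H <- matrix(1L, m, m)
    H[2L:m, 2L:m] <- core
    new("HadamardMatrix", order = m, entries = H)
}

#' Valid code lengths up to a limit
#'
#' Enumerates all \eqn{n \le} \code{limit} with \eqn{n} prime and
#' \eqn{n + 1} divisible by 4, i.e. the lengths for which the Paley
#' construction yields an illumination code.
#'
#' @param limit upper bound, at least 3.
#' @return increasing integer vector; begins 3, 7, 11, 19, 23, 31, 43.
#' @examples
#' validOrders(43)
#' @export
validOrders <- function(limit) {
    limit <- as.integer(limit)
    if (limit < 3L) stop("limit must be >= 3")
    n <- 3:limit
    n[vapply(n, isPrime, logical(1)) & (n + 1L) %% 4L == 0L]
}

#' Modified \{0,1\} code matrix from a Hadamard matrix
#'
#' Drops the all-ones border row and column of \eqn{H_m} and maps
#' \eqn{\pm 1 \to \{1, 0\}} via \eqn{(x + 1)/2}, yielding the symmetric
#' binary code \eqn{P_n} (\eqn{n = m - 1}). Column dot products are
#' \eqn{(n-1)/2} of a column with itself and \eqn{(n-3)/4} across distinct
#' columns -- 9 and 4 for \eqn{n = 19}.
#'
#' @param H a \linkS4class{HadamardMatrix}.
#' @return an \linkS4class{IlluminationCode}.
#' @examples
#' P <- codeMatrix(modifiedMatrix(paleyHadamard(20)))
#' crossprod(P[, 1])          # 9
#' crossprod(P[, 1], P[, 2])  # 4
#' @export
modifiedMatrix <- function(H) {
    stopifnot(is(H, "HadamardMatrix"))
    m <- codeOrder(H)
    P <- (hadamardEntries(H)[2L:m, 2L:m] + 1L) %/% 2L
    if (!all(P == t(P)))
        stop("symmetry violation: constructed P is not symmetric; ",
             "the Hadamard core uses an incompatible sign convention")
    new("IlluminationCode", n = m - 1L, P = P)
}

#' Convenience constructor for the illumination code of length n
#'
#' @param n valid code length (see \code{\link{validOrders}}).
#' @return an \linkS4class{IlluminationCode}.
#' @export
illuminationCodeFor <- function(n) {
    modifiedMatrix(paleyHadamard(as.integer(n) + 1L))
}

#' Assign code indices to the illumination cell lattice
#'
#' Cell \eqn{(i, j)} (0-based row, column) carries code
#' \eqn{k(i, j) = ((i q + j) \bmod n) + 1}. The same code recurs in the next
#' row at column offset \eqn{-q \pmod n}, so \code{q} controls how evenly
#' the decoded digital pinholes are spread; the approximate vertical pinhole
#' spacing is \code{round(n / q)} cells.
#'
#' @param n code length.
#' @param q layout parameter, \eqn{1 \le q < n}; default 5 pairs with the
#'   default \eqn{n = 19}.
#' @param cellsWide,cellsHigh lattice size in cells.
#' @param cellPx cell edge in camera pixels (default 3, a 1.95 um pinhole at
#'   the 0.65 um effective pixel).
#' @return a \linkS4class{PatternLayout}.
#' @examples
#' lay <- assignCodes(19, 5, 19, 19)
#' indexMap(lay)[1, 1]  # k(0,0) = 1
#' indexMap(lay)[2, 1]  # k(1,0) = 6 for q = 5
#' @export
assignCodes <- function(n, q, cellsWide, cellsHigh, cellPx = 3L) {
    n <- as.integer(n); q <- as.integer(q)
    cellsWide <- as.integer(cellsWide); cellsHigh <- as.integer(cellsHigh)
    cellPx <- as.integer(cellPx)
    if (cellsWide < 1L || cellsHigh < 1L || cellPx < 1L)
        stop("lattice dimensions and cellPx must be positive")
    if (q < 1L || q >= n)
        stop("q must satisfy 1 <= q < n")
    i <- matrix(seq_len(cellsHigh) - 1L, cellsHigh, cellsWide)
    j <- matrix(seq_len(cellsWide) - 1L, cellsHigh, cellsWide, byrow = TRUE)
    im <- ((i * q + j) %% n) + 1L
    new("PatternLayout", n = n, q = q, cellPx = cellPx,
        cellsWide = cellsWide, cellsHigh = cellsHigh,
        widthPx = cellsWide * cellPx, heightPx = cellsHigh * cellPx,
        indexMap = im, verticalSpacing = as.integer(round(n / q)))
}

#' Layout for a target pixel frame
#'
#' Builds the cell lattice covering a \code{widthPx} x \code{heightPx} pixel
#' frame; the lattice is cropped at the right/bottom edges when the frame is
#' not a multiple of \code{cellPx}.
#'
#' @inheritParams assignCodes
#' @param widthPx,heightPx frame size in pixels.
#' @return a \linkS4class{PatternLayout} whose pixel dimensions equal the
#'   requested frame.
#' @export
layoutForFrame <- function(n, q, widthPx, heightPx, cellPx = 3L) {
    widthPx <- as.integer(widthPx); heightPx <- as.integer(heightPx)
    if (widthPx < cellPx || heightPx < cellPx)
        stop("frame must be at least one cell in each dimension")
    lay <- assignCodes(n, q, ceiling(widthPx / cellPx),
                       ceiling(heightPx / cellPx), cellPx)
    lay@widthPx <- widthPx
    lay@heightPx <- heightPx
    lay
}

#' Generate the binary illumination pattern stack
#'
#' Upsamples the cell lattice to pixels and emits one binary frame per code:
#' frame \eqn{k} is on over cell \eqn{(i, j)} iff
#' \eqn{P[k(i,j), k] = 1}. Because every code has \eqn{(n-1)/2} on states,
#' the temporal mean over frames is spatially constant at
#' \eqn{(n-1)/(2n)} and each pixel is exposed \eqn{(n-1)/2} times per cycle
#' (9 for \eqn{n = 19}).
#'
#' @param code an \linkS4class{IlluminationCode}.
#' @param layout a \linkS4class{PatternLayout} with matching \eqn{n}.
#' @return a \linkS4class{PatternStack}.
#' @examples
#' stack <- generatePatternStack(illuminationCodeFor(19),
#'                               assignCodes(19, 5, 19, 19))
#' range(apply(frames(stack), c(1, 2), sum))  # 9 everywhere
#' @export
generatePatternStack <- function(code, layout) {
    stopifnot(is(code, "IlluminationCode"), is(layout, "PatternLayout"))
    if (codeOrder(code) != codeOrder(layout))
        stop("code and layout disagree on n")
    n <- codeOrder(code)
    h <- layout@heightPx; w <- layout@widthPx; cp <- layout@cellPx
    rowCell <- ((seq_len(h) - 1L) %/% cp) + 1L
    colCell <- ((seq_len(w) - 1L) %/% cp) + 1L
    pixIdx <- layout@indexMap[rowCell, colCell, drop = FALSE]
    P <- codeMatrix(code)
    fr <- array(0, c(h, w, n))
    for (k in seq_len(n))
        fr[, , k] <- P[pixIdx, k]
    new("PatternStack", frames = fr, layout = layout, code = code)
}

#' Find the self-similarity translation of a pattern stack
#'
#' The Paley code's cyclic structure makes every illumination frame a lattice
#' translation of a single master pattern: there is one cell shift
#' \eqn{\delta = (\Delta row, \Delta col)} such that translating frame
#' \eqn{k} by \eqn{\delta} (with the pattern's double n-cell periodicity)
#' reproduces frame \eqn{k + 1 \pmod n}, for every \eqn{k}. The shift is
#' found by exhaustive search over all \eqn{n^2} candidate cell shifts and
#' verified exactly on the n x n fundamental tile for all frames.
#'
#' @param stack a \linkS4class{PatternStack}.
#' @return integer vector \code{c(dRow, dCol)} in cells, with components in
#'   \eqn{(-n/2, n/2]} (the smallest-norm representative).
#' @examples
#' stack <- generatePatternStack(illuminationCodeFor(19),
#'                               assignCodes(19, 5, 19, 19))
#' selfSimilarityShift(stack)
#' @export
selfSimilarityShift <- function(stack) {
    stopifnot(is(stack, "PatternStack"))
    code <- illuminationCode(stack)
    lay <- patternLayout(stack)
    n <- codeOrder(code)
    q <- lay@q
    P <- codeMatrix(code)
    # Fundamental n x n cell tile (the pattern is n-periodic in both axes).
    i <- matrix(0L:(n - 1L), n, n)
    j <- t(i)
    idx <- ((i * q + j) %% n) + 1L
    tile <- function(k) P[idx, k]
    candidates <- expand.grid(dRow = 0L:(n - 1L), dCol = 0L:(n - 1L))
    signedNorm <- function(v) ifelse(v > n / 2, v - n, v)^2
    candidates <- candidates[order(signedNorm(candidates$dRow) +
                                   signedNorm(candidates$dCol)), ]
    found <- NULL
    for (s in seq_len(nrow(candidates))) {
        dr <- candidates$dRow[s]; dc <- candidates$dCol[s]
        ok <- TRUE
        for (k in seq_len(n)) {
            shifted <- translatePeriodic(matrix(tile(k), n, n), dr, dc)
            if (!all(shifted == tile(if (k == n) 1L else k + 1L))) {
                ok <- FALSE; break
            }
        }
        if (ok) { found <- c(dr, dc); break }
    }
    if (is.null(found))
        stop("no shift found: the code is not circulant ",
             "(wrong construction variant?)")
    signed <- ifelse(found > n / 2, found - n, found)
    as.integer(signed)
}

#' Exposure and frame accounting for a Hadamard acquisition
#'
#' For a length-\eqn{n} cycle each pixel is on during \eqn{(n-1)/2} frames
#' (the code's self-dot count), so coded illumination multiplies per-pixel
#' exposure by \eqn{(n-1)/2} relative to illuminating a single pinhole
#' pattern for the same frame time. With hologram speckle suppressed by
#' averaging \code{speckleShifts} pattern-preserving positions, the total
#' acquisition is \eqn{n \times} \code{speckleShifts} frames (76 for the
#' default \eqn{n = 19}, 4 shifts).
#'
#' @param n code length.
#' @param speckleShifts number of shifted acquisitions averaged (default 4).
#' @return list with \code{framesPerCycle}, \code{onFramesPerPixel},
#'   \code{totalFrames}, \code{exposureGain}.
#' @export
exposureAccounting <- function(n, speckleShifts = 4L) {
    n <- as.integer(n)
    list(framesPerCycle = n,
         onFramesPerPixel = (n - 1L) %/% 2L,
         totalFrames = n * as.integer(speckleShifts),
         exposureGain = (n - 1L) %/% 2L)
}

#' SNR ratio between two code lengths at fixed total acquisition time
#'
#' Per-pixel exposure over a full cycle scales as \eqn{(1 + 1/n)/2} of the
#' total time, so \eqn{SNR_{n_1}/SNR_{n_2} = \sqrt{(1 + 1/n_1)/(1 + 1/n_2)}},
#' approaching 1 as both lengths grow.
#'
#' @param n1,n2 code lengths.
#' @return the SNR ratio.
#' @examples
#' snrRatio(19, 3)
#' @export
snrRatio <- function(n1, n2) {
    sqrt((1 + 1 / n1) / (1 + 1 / n2))
}
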