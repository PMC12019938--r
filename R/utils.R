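# Internal numeric helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generators inside the
#' package never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

isPrime <- function(x) {
    x <- as.integer(x)
    if (x < 2L) return(FALSE)
    if (x < 4L) return(TRUE)
    if (x %% 2L == 0L) return(FALSE)
    d <- 3L
    while (d * d <= x) {
        if (x %% d == 0L) return(FALSE)
        d <- d + 2L
    }
    TRUE
}

# Modular exponentiation on small integers (p fits in double exactly).
powMod <- function(base, exp, mod) {
    result <- 1
    base <- base %% mod
    while (exp > 0) {
        if (exp %% 2 == 1) result <- (result * base) %% mod
        base <- (base * base) %% mod
        exp <- exp %/% 2
    }
    result
}

# Legendre symbol chi(a) mod odd prime p: +1 residue, -1 non-residue, 0 if p|a.
legendreSymbol <- function(a, p) {
    a <- a %% p
    if (a == 0) return(0L)
    r <- powMod(a, (p - 1) / 2, p)
    if (r == 1) 1L else -1L
}

# Zero-padded "same" convolution of an image with an odd-sized kernel,
# computed by FFT. The kernel center is its middle element, so a delta
# kernel is the identity. A dark field outside the field of view is assumed.
fftConvolveSame <- function(img, kernel) {
    stopifnot(is.matrix(img), is.matrix(kernel))
    kh <- nrow(kernel); kw <- ncol(kernel)
    if (kh %% 2L == 0L || kw %% 2L == 0L)
        stop("kernel dimensions must be odd")
    pl <- convPlan(dim(img), dim(kernel))
    convWithPlan(img, pl, fftPad(kernel, pl))
}

# Precompute padded FFT sizes and extraction offsets for repeated convolution
# of same-sized images with same-sized kernels.
convPlan <- function(dimImg, dimKer) {
    ph <- stats::nextn(dimImg[1L] + dimKer[1L] - 1L, c(2, 3, 5))
    pw <- stats::nextn(dimImg[2L] + dimKer[2L] - 1L, c(2, 3, 5))
    list(ph = ph, pw = pw,
         h = dimImg[1L], w = dimImg[2L],
         r0 = (dimKer[1L] + 1L) %/% 2L, c0 = (dimKer[2L] + 1L) %/% 2L)
}

fftPad <- function(x, plan) {
    out <- matrix(0, plan$ph, plan$pw)
    out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
    stats::fft(out)
}

convWithPlan <- function(img, plan, kernelFFT) {
    F1 <- fftPad(img, plan)
    full <- Re(stats::fft(F1 * kernelFFT, inverse = TRUE)) / (plan$ph * plan$pw)
    full[plan$r0:(plan$r0 + plan$h - 1L), plan$c0:(plan$c0 + plan$w - 1L)]
}

# Gaussian blur with kernel radius 3*sigma (sigma in pixels); sigma = 0 is
# the identity.
gaussianBlur <- function(img, sigma) {
    if (sigma <= 0) return(img)
    r <- max(1L, ceiling(3 * sigma))
    k <- kernelValues(gaussianPsf(sigma, radius = r))
    fftConvolveSame(img, k)
}

# Circular (periodic) integer translation of a matrix by (dRow, dCol):
# output[r, c] = input[r - dRow, c - dCol] with wrap.
translatePeriodic <- function(img, dRow, dCol) {
    h <- nrow(img); w <- ncol(img)
    ri <- ((seq_len(h) - 1L - round(dRow)) %% h) + 1L
    ci <- ((seq_len(w) - 1L - round(dCol)) %% w) + 1L
    img[ri, ci, drop = FALSE]
}

# Bilinear sampling of img at fractional (rows, cols); zero outside.
bilinearSample <- function(img, rows, cols) {
    h <- nrow(img); w <- ncol(img)
    r0 <- floor(rows); c0 <- floor(cols)
    fr <- rows - r0; fc <- cols - c0
    val <- numeric(length(rows))
    for (dr in 0:1) for (dc in 0:1) {
        rr <- r0 + dr; cc <- c0 + dc
        wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w & wgt > 0
        if (any(ok))
            val[ok] <- val[ok] + wgt[ok] * img[cbind(rr[ok], cc[ok])]
    }
    val
}

#' Rotate an image about its center
#'
#' Rotates image content counter-clockwise (positive angles, measured from the
#' +x/column axis with y pointing up) about the frame center, keeping the
#' output dimensions equal to the input. Pixels mapped from outside the frame
#' are zero. The identical center convention is used for intensities
#' (bilinear) and masks (nearest), so rotated stacks stay registered.
#'
#' @param img numeric matrix.
#' @param angleDeg rotation angle in degrees, counter-clockwise positive.
#' @param method \code{"bilinear"} for intensities, \code{"nearest"} for
#'   binary masks.
#' @return numeric matrix with the same dimensions as \code{img}.
#' @examples
#' m <- matrix(0, 32, 32); m[16, 10:22] <- 1
#' r <- rotateImage(m, 90)
#' @export
rotateImage <- function(img, angleDeg, method = c("bilinear", "nearest")) {
    method <- match.arg(method)
    h <- nrow(img); w <- ncol(img)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    a <- angleDeg * pi / 180
    co <- cos(a); si <- sin(a)
    rc <- expand.grid(r = seq_len(h), c = seq_len(w))
    X <- rc$c - cx
    Y <- cy - rc$r            # y up
    Xin <- X * co + Y * si    # rotate back by -angle
    Yin <- -X * si + Y * co
    rows <- cy - Yin
    cols <- Xin + cx
    vals <- if (method == "bilinear") {
        bilinearSample(img, rows, cols)
    } else {
        rr <- round(rows); cc <- round(cols)
        v <- numeric(length(rr))
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        v[ok] <- img[cbind(rr[ok], cc[ok])]
        v
    }
    matrix(vals, h, w)
}

# Place a small odd kernel into an odd support of size supp x supp, displaced
# by fractional (dRow, dCol) from the support center (bilinear splatting).
shiftIntoSupport <- function(kernel, supp, dRow, dCol) {
    out <- matrix(0, supp, supp)
    kc <- (dim(kernel) + 1L) %/% 2L
    ctr <- (supp + 1L) %/% 2L
    idx <- which(kernel != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(out)
    rows <- ctr + dRow + (idx[, 1L] - kc[1L])
    cols <- ctr + dCol + (idx[, 2L] - kc[2L])
    v <- kernel[idx]
    r0 <- floor(rows); c0 <- floor(cols)
    fr <- rows - r0; fc <- cols - c0
    for (dr in 0:1) for (dc in 0:1) {
        rr <- r0 + dr; cc <- c0 + dc
        wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
        ok <- rr >= 1 & rr <= supp & cc >= 1 & cc <= supp & wgt > 0
        if (any(ok)) {
            lin <- (cc[ok] - 1L) * supp + rr[ok]
            add <- tapply(v[ok] * wgt[ok], lin, sum)
            out[as.integer(names(add))] <- out[as.integer(names(add))] + add
        }
    }
    out
}

pearsonCor <- function(a, b) {
    stats::cor(as.vector(a), as.vector(b))
}

cosineSimilarity <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
}

# Logical matrix marking pixels at least `border` away from every edge.
interiorMask <- function(dims, border) {
    m <- matrix(FALSE, dims[1L], dims[2L])
    if (dims[1L] > 2 * border && dims[2L] > 2 * border)
        m[(border + 1L):(dims[1L] - border),
          (border + 1L):(dims[2L] - border)] <- TRUE
    m
}
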