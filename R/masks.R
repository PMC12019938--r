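# Hadamard decoding and construction of digital pinhole and slit masks.

#' Decode a frame stack against an illumination code
#'
#' Slice \eqn{r} of the result is the per-pixel projection of the temporal
#' signal onto column \eqn{r} of \eqn{P}:
#' \eqn{M(\cdot;r) = \sum_k I(\cdot;k) P[k, r]}. Decoding the ideal pattern
#' stack yields exactly the two code dot-product values, \eqn{(n-1)/2} at a
#' code's own pinhole cells and \eqn{(n-3)/4} elsewhere (9 and 4 for
#' \eqn{n = 19}).
#'
#' @param stack a \linkS4class{FrameStack} or \linkS4class{PatternStack}.
#' @param code an \linkS4class{IlluminationCode} with n matching the frame
#'   count.
#' @return a \linkS4class{DecodedStack}.
#' @export
decodeStack <- function(stack, code) {
    stopifnot(is(code, "IlluminationCode"))
    fr <- if (is(stack, "PatternStack")) frames(stack)
          else if (is(stack, "FrameStack")) frames(stack)
          else stop("stack must be a FrameStack or PatternStack")
    d <- dim(fr)
    n <- codeOrder(code)
    if (d[3L] != n)
        stop("frame-count mismatch: stack has ", d[3L], " frames, code n = ",
             n)
    flat <- matrix(fr, d[1L] * d[2L], n)
    dec <- array(flat %*% codeMatrix(code), c(d[1L], d[2L], n))
    path <- if (is(stack, "FrameStack")) stack@path else "normal"
    new("DecodedStack", values = dec, path = path)
}

# Per-pixel cross-talk offset image. Every code contributes (n-3)/4 to the
# decoded value of every other code, so the offset at a pixel equals
# (n-3)/(2(n-1)) times its temporal sum; for the ideal calibration stack
# this is exactly (n-3)/4 (= 4 for n = 19).
decodeOffsetImage <- function(stack, n) {
    fr <- if (is(stack, "FrameStack") || is(stack, "PatternStack"))
        frames(stack) else stack
    temporalSum <- apply(fr, c(1, 2), sum)
    temporalSum * (n - 3) / (2 * (n - 1))
}

#' Binarize decoded calibration data into a digital pinhole mask
#'
#' Subtracts the cross-talk offset \eqn{(n-3)/4}, normalizes by the ideal
#' range \eqn{(n-1)/2 - (n-3)/4 = (n+1)/4}, and marks pixels above the
#' threshold fraction. For an ideal (unblurred) calibration, slice \eqn{r}
#' marks exactly the cells with code index \eqn{r}.
#'
#' @param decoded a \linkS4class{DecodedStack} from a calibration
#'   acquisition.
#' @param code the \linkS4class{IlluminationCode} used.
#' @param thresholdFraction threshold on the range-normalized values
#'   (default 0.5); ignored for \code{method = "otsu"}.
#' @param method \code{"fraction"} (default) or \code{"otsu"}
#'   (data-driven threshold via \code{EBImage::otsu}).
#' @return a \linkS4class{PinholeMask}.
#' @export
binarizePinholes <- function(decoded, code, thresholdFraction = 0.5,
                             method = c("fraction", "otsu")) {
    stopifnot(is(decoded, "DecodedStack"), is(code, "IlluminationCode"))
    method <- match.arg(method)
    n <- codeOrder(code)
    offset <- (n - 3) / 4
    rng <- (n + 1) / 4
    vals <- decodedValues(decoded)
    if (max(vals) <= offset)
        stop("degenerate range: decoded maximum does not exceed the offset ",
             "(no signal)")
    norm <- (vals - offset) / rng
    thr <- if (method == "otsu") {
        # One global threshold over all slices.
        scaled <- matrix(pmin(pmax(norm, 0), 1), nrow = dim(vals)[1L])
        EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    } else thresholdFraction
    mask <- array(as.numeric(norm > thr), dim(vals))
    new("PinholeMask", mask = mask, offsetValue = offset,
        thresholdFraction = as.numeric(thr))
}

#' Digital slit mask from the spectral calibration acquisition
#'
#' Decodes the dispersed calibration stack, subtracts the cross-talk offset
#' and thresholds at a fraction of the observed (offset-subtracted) maximum.
#' Each resulting component is the pinhole footprint elongated along the
#' dispersion direction -- a digital slit defining where a pinhole's
#' spectrum lands on the detector.
#'
#' @param calSpectralStack the spectral-path calibration
#'   \linkS4class{FrameStack}.
#' @param code the \linkS4class{IlluminationCode}.
#' @param thresholdFraction fraction of the offset-subtracted maximum
#'   (default 0.2). The dispersed line ramps up over the first few pixels,
#'   and the pinhole sits at the ramp, so the threshold must stay below
#'   about a quarter of the line plateau for every slit to contain its
#'   pinhole; at the default geometry slits of the same code chain into
#'   connected diagonal runs whatever the threshold (the nearest same-code
#'   cell lies only ~4 px off the dispersion line).
#' @param lengthPx,angleDeg nominal slit geometry recorded on the mask.
#' @return a \linkS4class{SlitMask}.
#' @export
digitalSlits <- function(calSpectralStack, code, thresholdFraction = 0.2,
                         lengthPx = 40, angleDeg = -21.0) {
    stopifnot(is(calSpectralStack, "FrameStack"),
              is(code, "IlluminationCode"))
    if (calSpectralStack@path != "spectral")
        stop("digital slits require a spectral-path calibration stack")
    n <- codeOrder(code)
    dec <- decodeStack(calSpectralStack, code)
    offset <- decodeOffsetImage(calSpectralStack, n)
    vals <- decodedValues(dec)
    sub <- sweep(vals, c(1, 2), offset)
    mx <- max(sub)
    if (mx <= 0)
        stop("degenerate range: decoded maximum does not exceed the offset ",
             "(no signal)")
    mask <- array(as.numeric(sub > thresholdFraction * mx), dim(vals))
    new("SlitMask", mask = mask, offsetValue = (n - 3) / 4,
        thresholdFraction = thresholdFraction, lengthPx = lengthPx,
        angleDeg = angleDeg)
}
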