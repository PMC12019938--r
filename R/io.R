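# File round-trips: multi-page TIFF for stacks/kernels/cubes, YAML for
# layouts and configs, CSV for spectra, JSON for metrics and manifests.

stackToList <- function(arr) {
    lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
}

listToStack <- function(lst) {
    array(unlist(lst), c(dim(lst[[1L]]), length(lst)))
}

#' Write a pattern stack to TIFF with a YAML sidecar
#'
#' Frames are stored as 8-bit multi-page TIFF; the layout (n, q, cell size)
#' and the self-similarity shift go to \code{<path>.yaml}.
#'
#' @param stack a \linkS4class{PatternStack}.
#' @param path output TIFF path.
#' @param shift optional self-similarity shift to record.
#' @return \code{path}, invisibly.
#' @export
writePatternStack <- function(stack, path, shift = NULL) {
    stopifnot(is(stack, "PatternStack"))
    tiff::writeTIFF(stackToList(frames(stack)), path, bits.per.sample = 8L)
    lay <- patternLayout(stack)
    meta <- list(n = codeOrder(stack), q = lay@q, cellPx = lay@cellPx,
                 widthPx = lay@widthPx, heightPx = lay@heightPx)
    if (!is.null(shift)) meta$shift <- as.integer(shift)
    yaml::write_yaml(meta, paste0(path, ".yaml"))
    invisible(path)
}

#' Read a pattern stack written by \code{writePatternStack}
#'
#' Reconstructs the code and layout from the YAML sidecar and verifies the
#' stored frames against the regenerated stack.
#'
#' @param path TIFF path.
#' @return a \linkS4class{PatternStack}.
#' @export
readPatternStack <- function(path) {
    meta <- yaml::read_yaml(paste0(path, ".yaml"))
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- round(listToStack(pages))
    code <- illuminationCodeFor(meta$n)
    lay <- layoutForFrame(meta$n, meta$q, meta$widthPx, meta$heightPx,
                          meta$cellPx)
    stack <- generatePatternStack(code, lay)
    if (!all(frames(stack) == arr))
        warning("stored frames differ from the regenerated pattern stack")
    new("PatternStack", frames = arr, layout = lay, code = code)
}

#' Write a numeric image, stack or cube as 32-bit float TIFF
#'
#' Values are affinely mapped to [0, 1] for storage (the TIFF float writer
#' only defines that range); the original minimum and maximum go to a YAML
#' sidecar so \code{\link{readFloatTIFF}} restores the data.
#'
#' @param x matrix or 3D array.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFloatTIFF <- function(x, path) {
    lo <- min(x); hi <- max(x)
    scaled <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
    pages <- if (is.matrix(scaled)) list(scaled) else stackToList(scaled)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    yaml::write_yaml(list(min = lo, max = hi), paste0(path, ".yaml"))
    invisible(path)
}

#' Read a float TIFF written by \code{writeFloatTIFF}
#'
#' @param path TIFF path.
#' @return matrix (single page) or 3D array.
#' @export
readFloatTIFF <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    x <- if (length(pages) == 1L) pages[[1L]] else listToStack(pages)
    side <- paste0(path, ".yaml")
    if (file.exists(side)) {
        meta <- yaml::read_yaml(side)
        x <- x * (meta$max - meta$min) + meta$min
    }
    x
}

#' Write emission spectra as CSV
#'
#' Columns: \code{wavelength_nm}, one column per dye.
#'
#' @param spectra an \linkS4class{EmissionSpectra}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpectraCSV <- function(spectra, path) {
    Fm <- spectraMatrix(spectra)
    df <- data.frame(wavelength_nm = wavelengths(spectra), t(Fm))
    names(df)[-1L] <- paste0("dye", seq_len(nrow(Fm)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read emission spectra from CSV
#'
#' Accepts the format written by \code{\link{writeSpectraCSV}} (or measured
#' dye tables with a \code{wavelength_nm} column and one intensity column
#' per dye); rows are renormalized to unit sum.
#'
#' @param path CSV path.
#' @return an \linkS4class{EmissionSpectra}.
#' @export
readSpectraCSV <- function(path) {
    df <- utils::read.csv(path)
    if (!"wavelength_nm" %in% names(df))
        stop("CSV must contain a wavelength_nm column")
    wl <- df$wavelength_nm
    Fm <- t(as.matrix(df[setdiff(names(df), "wavelength_nm")]))
    Fm <- pmax(Fm, 0)
    Fm <- Fm / rowSums(Fm)
    new("EmissionSpectra", spectra = Fm, wavelengthsNm = wl)
}

#' Write a metrics report as JSON
#'
#' @param metrics a \linkS4class{MetricsReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsJSON <- function(metrics, path) {
    jsonlite::write_json(list(
        widefieldCor = metrics@widefieldCor,
        sectionedCor = metrics@sectionedCor,
        spectralCosines = metrics@spectralCosines,
        backgroundSuppression = metrics@backgroundSuppression
    ), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
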