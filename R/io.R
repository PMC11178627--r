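#' Read a radiograph into a GrayImage
#'
#' Reads PNG, TIFF or single-frame DICOM rasters and linearly rescales
#' intensities to \[0, 1\] using the full representable range of the
#' container bit depth (so identical scenes at different exposures remain
#' distinguishable). Multi-channel PNG/TIFF sources are converted by
#' averaging the colour channels (an alpha channel is ignored). DICOM pixel
#' values have rescale slope/intercept applied and are then windowed to the
#' stored min/max; `MONOCHROME1` (inverted) data are re-inverted so that
#' higher value = brighter. A DICOM frame with zero dynamic range reads as
#' an all-zero image with a warning.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, or `.dcm` file.
#' @return A [GrayImage-class].
#' @seealso [writeImage()]
#' @export
readGrayImage <- function(path) {
    if (!file.exists(path))
        stop("cannot read image: file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    m <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        dcm = ,
        dicom = return(GrayImage(.readDicomMatrix(path))),
        stop("unsupported image format '.", ext, "' for ", path))
    if (length(dim(m)) == 3L) {
        nc <- dim(m)[3]
        keep <- seq_len(min(nc, 3L))   # drop alpha if present
        m <- apply(m[, , keep, drop = FALSE], c(1, 2), mean)
    }
    GrayImage(clip01(m))
}

#' Write an image to PNG or TIFF
#'
#' Intensities are quantised as `round(v * (2^bits - 1))`, so a subsequent
#' [readGrayImage()] recovers them within `1 / (2^bits - 1)`. PNG output is
#' 8-bit; 16-bit output is supported through TIFF. A
#' [MultiChannelImage-class] is written as a 3-plane raster.
#'
#' @param img a [GrayImage-class] or [MultiChannelImage-class].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bitDepth 8 or 16 (16 requires TIFF).
#' @return Invisibly, `path`.
#' @export
writeImage <- function(img, path, bitDepth = 8L) {
    stopifnot(bitDepth %in% c(8L, 16L))
    ext <- tolower(tools::file_ext(path))
    mx <- 2^bitDepth - 1
    quant <- function(m) round(m * mx) / mx
    dat <- if (is(img, "MultiChannelImage")) {
        d <- dim(img)
        a <- array(0, c(d[1], d[2], 3))
        for (i in 1:3) a[, , i] <- quant(img@channels[[i]]@pixels)
        a
    } else if (is(img, "GrayImage")) {
        quant(img@pixels)
    } else stop("img must be a GrayImage or MultiChannelImage")
    ok <- switch(ext,
        png = {
            if (bitDepth != 8L)
                stop("PNG output is 8-bit; use TIFF for 16-bit")
            try(png::writePNG(dat, path), silent = TRUE)
        },
        tif = ,
        tiff = try(tiff::writeTIFF(dat, path,
                                   bits.per.sample = as.integer(bitDepth)),
                   silent = TRUE),
        stop("unsupported output format '.", ext, "' for ", path))
    if (inherits(ok, "try-error"))
        stop("cannot write image to ", path)
    invisible(path)
}

#' Replicate a single channel into a three-channel stack
#'
#' Classifier backbones expect three input planes; this produces them by
#' replication. Each output channel equals the input elementwise.
#'
#' @param img a [GrayImage-class].
#' @return A [MultiChannelImage-class].
#' @examples
#' mci <- toThreeChannel(GrayImage(matrix(0.7, 8, 8)))
#' @export
toThreeChannel <- function(img) {
    stopifnot(is(img, "GrayImage"))
    MultiChannelImage(list(img, img, img))
}
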