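#' Laplacian-kernel sharpening
#'
#' Convolves the image with an intensity-preserving 3x3 kernel (entries sum
#' to 1) under symmetric boundary extension, then clips to \[0, 1\]. The
#' default kernel is the classic Laplacian-based sharpen
#' `[[0,-1,0],[-1,5,-1],[0,-1,0]]`, which leaves flat regions untouched and
#' amplifies local intensity steps.
#'
#' @param img a [GrayImage-class].
#' @param kernel 3x3 numeric matrix summing to 1 (within 1e-9).
#' @param clip if `TRUE` (default) clip to \[0, 1\] and return a GrayImage;
#'   if `FALSE` return the raw convolved matrix (useful for diagnostics).
#' @return A [GrayImage-class], or a numeric matrix when `clip = FALSE`.
#' @examples
#' img <- GrayImage(matrix(0.5, 16, 16))
#' identical(pixels(sharpen(img)), pixels(img))
#' @export
sharpen <- function(img, kernel = sharpenKernel(), clip = TRUE) {
    stopifnot(is(img, "GrayImage"))
    if (abs(sum(kernel) - 1) > 1e-9)
        stop("sharpening kernel entries must sum to 1 (within 1e-9)")
    out <- conv2dReflect(img@pixels, kernel)
    if (!clip) return(out)
    GrayImage(clip01(out))
}

#' @rdname sharpen
#' @export
sharpenKernel <- function() {
    matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3, byrow = TRUE)
}

# Histogram over nbins equal bins on [0,1]; value v falls in bin
# floor(v*nbins)+1, with v = 1 assigned to the top bin.
.intensityBin <- function(v, nbins) {
    pmin(floor(v * nbins) + 1L, nbins)
}

#' Global histogram equalisation
#'
#' Maps intensities through the normalised cumulative histogram:
#' `out(v) = (cdf(v) - cdf_min) / (1 - cdf_min)`, with `cdf_min` the CDF at
#' the lowest occupied bin, so the darkest occupied level maps to 0 and the
#' brightest to 1. The mapping is monotone non-decreasing in input
#' intensity. A constant image (degenerate CDF) is returned unchanged.
#'
#' @param img a [GrayImage-class].
#' @param nbins number of histogram bins (default 256, minimum 16).
#' @return A [GrayImage-class].
#' @examples
#' img <- GrayImage(matrix(seq(0, 1, length.out = 64), 8, 8))
#' eq <- histEqualize(img)
#' @export
histEqualize <- function(img, nbins = 256L) {
    stopifnot(is(img, "GrayImage"), nbins >= 16L)
    v <- img@pixels
    b <- .intensityBin(v, nbins)
    h <- tabulate(b, nbins)
    cdf <- cumsum(h) / length(v)
    cdfmin <- cdf[which(h > 0)[1]]
    if (1 - cdfmin <= 0) return(img)    # constant image: identity
    GrayImage(clip01(matrix((cdf[b] - cdfmin) / (1 - cdfmin), nrow(v))))
}

#' CLAHE parameter set
#'
#' @param tilesY,tilesX tile grid size (default 8x8); edge tiles may be
#'   smaller when the image size is not divisible.
#' @param clipLimit histogram clip limit relative to the mean bin height of
#'   a uniform histogram (default 2.0), or `Inf` for unclipped adaptive
#'   equalisation.
#' @param nbins histogram bins per tile (default 256, minimum 16).
#' @return A named list of validated CLAHE parameters.
#' @seealso [clahe()]
#' @export
claheParams <- function(tilesY = 8L, tilesX = 8L, clipLimit = 2.0,
                        nbins = 256L) {
    stopifnot(tilesY >= 1L, tilesX >= 1L, clipLimit > 0, nbins >= 16L)
    list(tilesY = as.integer(tilesY), tilesX = as.integer(tilesX),
         clipLimit = clipLimit, nbins = as.integer(nbins))
}

# Per-tile equalisation LUT with clipping: histogram bins above
# clipLimit * npix/nbins are truncated and the excess is redistributed
# uniformly (single pass). Degenerate tiles (all mass in one bin) are
# flagged and mapped by the identity.
.tileLut <- function(v, nbins, clipLimit) {
    b <- .intensityBin(v, nbins)
    h <- tabulate(b, nbins)
    occ <- which(h > 0)
    if (length(occ) <= 1L)
        return(list(lut = numeric(nbins), degenerate = TRUE))
    if (is.finite(clipLimit)) {
        limit <- clipLimit * length(v) / nbins
        excess <- sum(pmax(h - limit, 0))
        h <- pmin(h, limit) + excess / nbins
    }
    cdf <- cumsum(h) / sum(h)
    cdfmin <- cdf[which(h > 0)[1]]
    if (1 - cdfmin <= 0)
        return(list(lut = numeric(nbins), degenerate = TRUE))
    list(lut = clip01((cdf - cdfmin) / (1 - cdfmin)), degenerate = FALSE)
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' The image is partitioned into a `tilesY` x `tilesX` grid; each tile gets
#' its own clipped-histogram equalisation mapping (clipped excess
#' redistributed uniformly across all bins), and each pixel is mapped by
#' bilinear interpolation of the mappings of the four surrounding tile
#' centres (clamped at the image border). With a 1x1 grid and
#' `clipLimit = Inf` this reduces to global [histEqualize()]. Degenerate
#' (constant) tiles map by the identity, so a constant image is returned
#' unchanged.
#'
#' @param img a [GrayImage-class].
#' @param params a list from [claheParams()].
#' @return A [GrayImage-class].
#' @examples
#' img <- GrayImage(matrix(runif(32 * 32), 32, 32))
#' out <- clahe(img, claheParams(tilesY = 2, tilesX = 2))
#' @export
clahe <- function(img, params = claheParams()) {
    stopifnot(is(img, "GrayImage"))
    v <- img@pixels
    h <- nrow(v); w <- ncol(v)
    ty <- params$tilesY; tx <- params$tilesX; nbins <- params$nbins
    if (ty > h || tx > w)
        stop("tile grid larger than the image")
    # tile extents by even partition; edge tiles absorb the remainder
    rowBreaks <- floor(seq(0, h, length.out = ty + 1))
    colBreaks <- floor(seq(0, w, length.out = tx + 1))
    cy <- (rowBreaks[-1] + rowBreaks[-(ty + 1)] + 1) / 2
    cx <- (colBreaks[-1] + colBreaks[-(tx + 1)] + 1) / 2
    lut <- matrix(0, nbins, ty * tx)
    degen <- logical(ty * tx)
    for (j in seq_len(tx)) {
        for (i in seq_len(ty)) {
            tv <- v[(rowBreaks[i] + 1):rowBreaks[i + 1],
                    (colBreaks[j] + 1):colBreaks[j + 1]]
            tl <- .tileLut(tv, nbins, params$clipLimit)
            idx <- (j - 1L) * ty + i
            lut[, idx] <- tl$lut
            degen[idx] <- tl$degenerate
        }
    }
    # neighbouring tile centres and interpolation weights per row / column
    lo <- function(pos, centres) {
        i <- findInterval(pos, centres)
        pmin(pmax(i, 1L), length(centres))
    }
    t0y <- lo(seq_len(h), cy); t1y <- pmin(t0y + 1L, ty)
    t0x <- lo(seq_len(w), cx); t1x <- pmin(t0x + 1L, tx)
    wy <- ifelse(t1y > t0y,
                 (seq_len(h) - cy[t0y]) / (cy[t1y] - cy[t0y]), 0)
    wy <- pmin(pmax(wy, 0), 1)
    wx <- ifelse(t1x > t0x,
                 (seq_len(w) - cx[t0x]) / (cx[t1x] - cx[t0x]), 0)
    wx <- pmin(pmax(wx, 0), 1)
    bins <- .intensityBin(v, nbins)
    mapVal <- function(tyIdx, txIdx) {
        tix <- (rep(txIdx, each = h) - 1L) * ty + rep(tyIdx, w)
        m <- lut[cbind(as.vector(bins), tix)]
        d <- degen[tix]
        m[d] <- as.vector(v)[d]
        matrix(m, h, w)
    }
    WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
    out <- (1 - WY) * (1 - WX) * mapVal(t0y, t0x) +
           (1 - WY) * WX       * mapVal(t0y, t1x) +
           WY       * (1 - WX) * mapVal(t1y, t0x) +
           WY       * WX       * mapVal(t1y, t1x)
    GrayImage(clip01(out))
}

#' Unsharp masking
#'
#' Sharpens by adding back the detail lost to a Gaussian blur:
#' `out = clip(img + amount * (img - blur(img, sigma)), 0, 1)`. The blur is
#' separable with symmetric boundaries and a truncated kernel radius of
#' `ceil(3 * sigma)`. `amount = 0` is the exact identity.
#'
#' @param img a [GrayImage-class].
#' @param sigma Gaussian blur standard deviation in pixels (> 0).
#' @param amount non-negative detail gain.
#' @param clip if `FALSE`, return the raw (unclipped) matrix.
#' @return A [GrayImage-class], or a numeric matrix when `clip = FALSE`.
#' @export
unsharpMask <- function(img, sigma = 1.0, amount = 1.0, clip = TRUE) {
    stopifnot(is(img, "GrayImage"), sigma > 0, amount >= 0)
    v <- img@pixels
    out <- v + amount * (v - gaussianBlurMat(v, sigma))
    if (!clip) return(out)
    GrayImage(clip01(out))
}

#' Percentile dynamic-range compression
#'
#' Linearly rescales so that the `lowPct` percentile maps to 0 and the
#' `highPct` percentile to 1, clipping the tails. With percentiles 0/100
#' this is a min-max stretch. An image with no dynamic range between the
#' two percentiles is returned unchanged.
#'
#' @param img a [GrayImage-class].
#' @param lowPct lower percentile in \[0, 50) (default 2).
#' @param highPct upper percentile in (50, 100\] (default 98).
#' @return A [GrayImage-class].
#' @export
compressHistogram <- function(img, lowPct = 2, highPct = 98) {
    stopifnot(is(img, "GrayImage"),
              lowPct >= 0, lowPct < 50, highPct > 50, highPct <= 100,
              lowPct < highPct)
    v <- img@pixels
    q <- quantile(v, c(lowPct, highPct) / 100, names = FALSE)
    if (q[2] <= q[1]) return(img)
    GrayImage(clip01((v - q[1]) / (q[2] - q[1])))
}

#' Intensity inversion
#'
#' `out = 1 - img`; an exact involution.
#'
#' @param img a [GrayImage-class].
#' @return A [GrayImage-class].
#' @export
invertImage <- function(img) {
    stopifnot(is(img, "GrayImage"))
    GrayImage(1 - img@pixels)
}
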