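# Deterministic geometric/intensity transforms plus their randomised
# wrappers. The deterministic cores are exported so tests and audit logs
# can force exact magnitudes.

#' Translate an image by whole pixels
#'
#' Shifts the raster by `dy` rows (positive = down) and `dx` columns
#' (positive = right); vacated pixels are filled with 0, matching the
#' collimated black border of radiographs.
#'
#' @param img a [GrayImage-class].
#' @param dy,dx integer shifts in pixels.
#' @return A [GrayImage-class].
#' @export
translateImage <- function(img, dy, dx) {
    stopifnot(is(img, "GrayImage"))
    v <- img@pixels
    h <- nrow(v); w <- ncol(v)
    out <- matrix(0, h, w)
    srcR <- seq_len(h) - dy
    srcC <- seq_len(w) - dx
    okR <- srcR >= 1L & srcR <= h
    okC <- srcC >= 1L & srcC <= w
    if (any(okR) && any(okC))
        out[okR, okC] <- v[srcR[okR], srcC[okC], drop = FALSE]
    GrayImage(out)
}

#' Rotate an image about its centre
#'
#' Resamples on the output grid with out-of-frame pixels filled with 0. At
#' multiples of 90 degrees on a square image the nearest-neighbour method
#' reproduces the exact grid symmetry.
#'
#' @param img a [GrayImage-class].
#' @param degrees rotation angle in degrees.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A [GrayImage-class].
#' @export
rotateImage <- function(img, degrees, method = c("bilinear", "nearest")) {
    stopifnot(is(img, "GrayImage"))
    method <- match.arg(method)
    v <- img@pixels
    h <- nrow(v); w <- ncol(v)
    th <- degrees * pi / 180
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    R <- matrix(seq_len(h), h, w)
    C <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- cy + cos(th) * (R - cy) - sin(th) * (C - cx)
    xs <- cx + sin(th) * (R - cy) + cos(th) * (C - cx)
    # snap coordinates that are numerically on the grid (e.g. multiples of
    # 90 degrees) so boundary pixels are not lost to rounding error
    snap <- function(z) { zr <- round(z); ifelse(abs(z - zr) < 1e-9, zr, z) }
    ys <- snap(ys); xs <- snap(xs)
    out <- matrix(0, h, w)
    if (method == "nearest") {
        yi <- round(ys); xi <- round(xs)
        ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
        out[ok] <- v[cbind(yi[ok], xi[ok])]
    } else {
        y0 <- floor(ys); x0 <- floor(xs)
        wy <- ys - y0; wx <- xs - x0
        ok <- y0 >= 1 & (y0 + 1) <= h & x0 >= 1 & (x0 + 1) <= w
        # interior bilinear blend; edge samples handled below
        idx <- which(ok)
        if (length(idx)) {
            out[idx] <-
                (1 - wy[idx]) * (1 - wx[idx]) * v[cbind(y0[idx], x0[idx])] +
                (1 - wy[idx]) * wx[idx] * v[cbind(y0[idx], x0[idx] + 1)] +
                wy[idx] * (1 - wx[idx]) * v[cbind(y0[idx] + 1, x0[idx])] +
                wy[idx] * wx[idx] * v[cbind(y0[idx] + 1, x0[idx] + 1)]
        }
        # samples landing exactly on the last row/column
        edge <- which(!ok & ys >= 1 & ys <= h & xs >= 1 & xs <= w)
        if (length(edge)) {
            yc <- pmin(pmax(round(ys[edge]), 1), h)
            xc <- pmin(pmax(round(xs[edge]), 1), w)
            out[edge] <- v[cbind(yc, xc)]
        }
    }
    GrayImage(clip01(out))
}

#' Flip an image
#'
#' Reverses column order (`"horizontal"`) or row order (`"vertical"`).
#' An exact involution; a horizontal followed by a vertical flip equals a
#' 180-degree rotation.
#'
#' @param img a [GrayImage-class].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return A [GrayImage-class].
#' @export
flipImage <- function(img, axis = c("horizontal", "vertical")) {
    stopifnot(is(img, "GrayImage"))
    axis <- match.arg(axis)
    v <- img@pixels
    out <- if (axis == "horizontal") v[, rev(seq_len(ncol(v))), drop = FALSE]
           else v[rev(seq_len(nrow(v))), , drop = FALSE]
    GrayImage(out)
}

#' Crop a square window and resize back to the original frame
#'
#' @param img a [GrayImage-class].
#' @param top,left 1-based top-left corner of the window.
#' @param size window side in pixels.
#' @return A [GrayImage-class] with the original dimensions.
#' @export
cropResize <- function(img, top, left, size) {
    stopifnot(is(img, "GrayImage"))
    v <- img@pixels
    h <- nrow(v); w <- ncol(v)
    stopifnot(size >= 2L, top >= 1L, left >= 1L,
              top + size - 1L <= h, left + size - 1L <= w)
    win <- v[top:(top + size - 1L), left:(left + size - 1L), drop = FALSE]
    GrayImage(clip01(resizeBilinearMat(win, h, w)))
}

#' Occlude a rectangle
#'
#' Sets the given axis-aligned rectangle to 0; all other pixels are
#' unchanged.
#'
#' @param img a [GrayImage-class].
#' @param top,left 1-based top-left corner.
#' @param height,width rectangle size in pixels.
#' @return A [GrayImage-class].
#' @export
occludeRect <- function(img, top, left, height, width) {
    stopifnot(is(img, "GrayImage"))
    v <- img@pixels
    stopifnot(top >= 1L, left >= 1L,
              top + height - 1L <= nrow(v), left + width - 1L <= ncol(v))
    v[top:(top + height - 1L), left:(left + width - 1L)] <- 0
    GrayImage(v)
}

#' Stochastic augmentations
#'
#' Randomised wrappers around the deterministic transforms, drawing their
#' magnitudes from the current RNG stream:
#' \describe{
#'   \item{`randomTranslate`}{integer shifts `dy`, `dx` drawn independently
#'     and uniformly from `[-round(maxFrac * H), round(maxFrac * H)]` and
#'     the analogous column range.}
#'   \item{`randomCropResize`}{a `cropSize` x `cropSize` window at a
#'     uniformly random valid position, resized back to the input frame by
#'     bilinear interpolation.}
#'   \item{`randomRotate`}{angle drawn uniformly from
#'     `[-maxDeg, +maxDeg]`, bilinear resampling.}
#'   \item{`randomOcclude`}{one rectangle of `round(areaFrac * H * W)`
#'     pixels (aspect ratio uniform in \[0.5, 2\], clipped to the frame) at
#'     a uniformly random position is set to 0.}
#'   \item{`randomNoise`}{adds i.i.d. zero-mean Gaussian noise with sd
#'     `sigma`, then clips to \[0, 1\].}
#' }
#'
#' @param img a [GrayImage-class].
#' @param maxFrac maximum shift as a fraction of image length, in
#'   \[0, 0.5\].
#' @param cropSize crop window side in pixels (at most `min(H, W)`).
#' @param maxDeg maximum rotation in degrees.
#' @param areaFrac occluded fraction of image area, in (0, 1).
#' @param sigma Gaussian noise standard deviation (> 0).
#' @return A [GrayImage-class].
#' @name random-augmentations
NULL

#' @rdname random-augmentations
#' @export
randomTranslate <- function(img, maxFrac = 0.10) {
    stopifnot(maxFrac >= 0, maxFrac <= 0.5)
    d <- dim(img)
    my <- round(maxFrac * d[1]); mx <- round(maxFrac * d[2])
    dy <- if (my > 0) sample(seq(-my, my), 1L) else 0L
    dx <- if (mx > 0) sample(seq(-mx, mx), 1L) else 0L
    translateImage(img, dy, dx)
}

#' @rdname random-augmentations
#' @export
randomCropResize <- function(img, cropSize = 159L) {
    d <- dim(img)
    if (cropSize > min(d))
        stop("cropSize exceeds the smaller image dimension")
    top <- sample.int(d[1] - cropSize + 1L, 1L)
    left <- sample.int(d[2] - cropSize + 1L, 1L)
    cropResize(img, top, left, cropSize)
}

#' @rdname random-augmentations
#' @export
randomRotate <- function(img, maxDeg = 20) {
    stopifnot(maxDeg >= 0)
    rotateImage(img, runif(1, -maxDeg, maxDeg))
}

#' @rdname random-augmentations
#' @export
randomOcclude <- function(img, areaFrac = 0.05) {
    stopifnot(areaFrac > 0, areaFrac < 1)
    d <- dim(img)
    area <- round(areaFrac * d[1] * d[2])
    r <- runif(1, 0.5, 2)
    rh <- max(1L, min(d[1], as.integer(round(sqrt(area * r)))))
    rw <- max(1L, min(d[2], as.integer(round(area / rh))))
    top <- sample.int(d[1] - rh + 1L, 1L)
    left <- sample.int(d[2] - rw + 1L, 1L)
    occludeRect(img, top, left, rh, rw)
}

#' @rdname random-augmentations
#' @export
randomNoise <- function(img, sigma = 0.05) {
    stopifnot(sigma > 0)
    v <- img@pixels
    GrayImage(clip01(v + matrix(rnorm(length(v), 0, sigma), nrow(v))))
}
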