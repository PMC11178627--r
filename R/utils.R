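# Internal numerical helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Derive reproducible sub-seeds from a parent seed without sharing streams.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Symmetric (edge-repeating) index extension: 2,1 | 1..n | n,n-1.
padIdx <- function(n, r) {
    if (r == 0L) return(seq_len(n))
    c(rev(seq_len(min(r, n))), seq_len(n), n + 1L - seq_len(min(r, n)))
}

# Sliding-window correlation of a matrix with a small odd-sized kernel under
# symmetric boundary extension. For symmetric kernels this coincides with
# convolution.
conv2dReflect <- function(m, kernel) {
    kh <- nrow(kernel); kw <- ncol(kernel)
    stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
    ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
    p <- m[padIdx(nrow(m), ry), padIdx(ncol(m), rx), drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
            if (kernel[i, j] == 0) next
            out <- out + kernel[i, j] *
                p[i:(i + nrow(m) - 1L), j:(j + ncol(m) - 1L), drop = FALSE]
        }
    }
    out
}

gaussianKernel1d <- function(sigma) {
    r <- ceiling(3 * sigma)
    x <- seq(-r, r)
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

# Separable Gaussian blur, symmetric boundaries, kernel radius ceil(3*sigma).
gaussianBlurMat <- function(m, sigma) {
    k <- gaussianKernel1d(sigma)
    r <- (length(k) - 1L) %/% 2L
    # rows (vertical pass)
    p <- m[padIdx(nrow(m), r), , drop = FALSE]
    v <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
        v <- v + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
    # columns (horizontal pass)
    p <- v[, padIdx(ncol(m), r), drop = FALSE]
    h <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
        h <- h + k[i] * p[, i:(i + ncol(m) - 1L), drop = FALSE]
    h
}

# Bilinear resize with corner-aligned sampling: resizing to the same shape
# is the exact identity.
resizeBilinearMat <- function(m, oh, ow) {
    h <- nrow(m); w <- ncol(m)
    sy <- if (oh > 1L) (seq_len(oh) - 1) * (h - 1) / (oh - 1) + 1 else (h + 1) / 2
    sx <- if (ow > 1L) (seq_len(ow) - 1) * (w - 1) / (ow - 1) + 1 else (w + 1) / 2
    y0 <- pmin(floor(sy), h - 1L); y0 <- pmax(y0, 1L); y1 <- y0 + 1L
    x0 <- pmin(floor(sx), w - 1L); x0 <- pmax(x0, 1L); x1 <- x0 + 1L
    wy <- sy - y0; wx <- sx - x0
    ((1 - wy) %o% (1 - wx)) * m[y0, x0, drop = FALSE] +
    ((1 - wy) %o% wx)       * m[y0, x1, drop = FALSE] +
    (wy %o% (1 - wx))       * m[y1, x0, drop = FALSE] +
    (wy %o% wx)             * m[y1, x1, drop = FALSE]
}

# Anti-aliased downsampling: a Gaussian pre-filter at sigma = 0.5 * scale
# factor suppresses frequencies the coarser grid cannot represent, then
# bilinear resampling. Upsampling and near-identity resizes skip the filter.
antialiasResize <- function(m, oh, ow) {
    fac <- max(nrow(m) / oh, ncol(m) / ow)
    if (fac > 1.5) m <- gaussianBlurMat(m, 0.5 * fac)
    resizeBilinearMat(m, oh, ow)
}

# Chebyshev (square structuring element) binary dilation by `radius` pixels.
dilateMask <- function(mask, radius) {
    h <- nrow(mask); w <- ncol(mask)
    out <- matrix(FALSE, h, w)
    for (dy in -radius:radius) {
        ri <- seq_len(h) + dy
        rok <- ri >= 1L & ri <= h
        for (dx in -radius:radius) {
            ci <- seq_len(w) + dx
            cok <- ci >= 1L & ci <= w
            out[rok, cok] <- out[rok, cok] |
                mask[ri[rok], ci[cok], drop = FALSE]
        }
    }
    out
}
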