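# Synthetic abdominal-radiograph phantoms: a stylised neonatal AXR scene
# (bright body ellipse, spine column, bowel-gas lucencies) with
# class-dependent lesion patterns and a ground-truth lesion mask. The
# contract is controllable class structure at tunable subtlety, not
# anatomical realism.

.inEllipse <- function(R, C, cy, cx, ry, rx) {
    ((R - cy) / ry)^2 + ((C - cx) / rx)^2 <= 1
}

# Fixed geometric zones shared by the generator and the feature extractor:
# the bowel region (where gas and mottled mNEC lucencies live) and the
# sub-diaphragmatic band (where the sNEC crescent lives).
phantomZones <- function(h, w) {
    R <- matrix(seq_len(h), h, w)
    C <- matrix(seq_len(w), h, w, byrow = TRUE)
    body <- .inEllipse(R, C, 0.52 * h, 0.50 * w, 0.42 * h, 0.36 * w)
    list(
        body = body,
        bowel = .inEllipse(R, C, 0.58 * h, 0.50 * w, 0.28 * h, 0.27 * w),
        band = body & R >= 0.20 * h & R <= 0.38 * h)
}

#' Generate one synthetic abdominal radiograph
#'
#' Renders a stylised low-contrast AXR: dark background (0.05), bright
#' body ellipse (0.55), brighter spine column (0.75) and 6-10 jittered
#' elliptical bowel-gas lucencies (about -0.15). The whole anatomy sits
#' at a per-image positioning offset (uniform within 3% of the frame),
#' emulating the patient-positioning variability of mobile neonatal
#' radiographs. Class-specific additions:
#' `NP` none; `mNEC` 3-6 clusters of small mottled lucencies inside the
#' bowel region at intensity `-lesionContrast * 0.3`; `sNEC` one large
#' sub-diaphragmatic lucent crescent at `-lesionContrast * 0.4`. The scene
#' is then Gaussian-blurred (`blurSigma`), Gaussian noise (`noiseSigma`)
#' is added, and intensities are clipped to \[0, 1\].
#'
#' Scene geometry, lesion geometry and noise are drawn from three
#' sub-streams derived from `spec@seed`, so the same spec always yields a
#' bit-identical image, and setting `lesionContrast = 0` yields an image
#' identical (before noise) to the NP phantom with the same seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `image` (a [GrayImage-class]) and `mask`
#'   (logical matrix marking class-specific lesion pixels; all `FALSE` for
#'   NP).
#' @examples
#' ph <- generatePhantom(PhantomSpec("sNEC", seed = 11))
#' mean(ph$mask)
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    h <- spec@height; w <- spec@width
    seeds <- deriveSeeds(spec@seed, 3L)
    R <- matrix(seq_len(h), h, w)
    C <- matrix(seq_len(w), h, w, byrow = TRUE)
    img <- matrix(0.05, h, w)
    # patient positioning jitter: the whole anatomy sits at a per-image
    # offset, as it does on mobile neonatal radiographs
    withSeed(seeds[1], {
        jy <- runif(1, -0.03, 0.03)
        jx <- runif(1, -0.03, 0.03)
        body <- .inEllipse(R, C, (0.52 + jy) * h, (0.50 + jx) * w,
                           0.42 * h, 0.36 * w)
        img[body] <- 0.55
        spine <- abs(C - (0.50 + jx) * w) <= 0.035 * w & body
        img[spine] <- 0.75
        # bowel gas lucencies (common to all classes)
        nGas <- sample(6:10, 1L)
        for (g in seq_len(nGas)) {
            cy <- (0.58 + jy + runif(1, -0.20, 0.20)) * h
            cx <- (0.50 + jx + runif(1, -0.20, 0.20)) * w
            ry <- runif(1, 0.03, 0.07) * h
            rx <- runif(1, 0.03, 0.07) * w
            depth <- 0.15 + runif(1, -0.03, 0.03)
            sel <- .inEllipse(R, C, cy, cx, ry, rx) & body
            img[sel] <- img[sel] - depth
        }
    })
    mask <- matrix(FALSE, h, w)
    if (spec@label != "NP") {
        withSeed(seeds[2], {
            if (spec@label == "mNEC") {
                nCl <- sample(3:6, 1L)
                for (k in seq_len(nCl)) {
                    cy <- (0.58 + jy + runif(1, -0.18, 0.18)) * h
                    cx <- (0.50 + jx + runif(1, -0.18, 0.18)) * w
                    nS <- sample(4:8, 1L)
                    for (s in seq_len(nS)) {
                        sy <- cy + runif(1, -0.05, 0.05) * h
                        sx <- cx + runif(1, -0.05, 0.05) * w
                        sr <- runif(1, 0.008, 0.02) * h
                        mask <- mask | (.inEllipse(R, C, sy, sx, sr, sr) &
                                        body)
                    }
                }
                img[mask] <- img[mask] - spec@lesionContrast * 0.3
            } else {   # sNEC: sub-diaphragmatic lucent crescent
                cy <- (runif(1, 0.26, 0.32) + jy) * h
                cx <- (runif(1, 0.40, 0.60) + jx) * w
                outer <- .inEllipse(R, C, cy, cx, 0.09 * h, 0.20 * w)
                inner <- .inEllipse(R, C, cy + 0.045 * h, cx,
                                    0.09 * h, 0.21 * w)
                mask <- outer & !inner & body
                img[mask] <- img[mask] - spec@lesionContrast * 0.4
            }
        })
    }
    img <- gaussianBlurMat(clip01(img), spec@blurSigma)
    if (spec@noiseSigma > 0) {
        withSeed(seeds[3], {
            img <- img + matrix(rnorm(h * w, 0, spec@noiseSigma), h, w)
        })
    }
    list(image = GrayImage(clip01(img)), mask = mask)
}

#' Generate a balanced phantom dataset on disk
#'
#' Writes `3 * nPerClass` phantom PNGs (plus lesion-mask PNGs for mNEC and
#' sNEC) with per-image seeds `baseSeed + index`, and a manifest CSV with
#' header `path,label,seed,lesion_contrast,mask_path`. Labels are exactly
#' balanced.
#'
#' @param nPerClass images per class (>= 1).
#' @param baseSeed integer base seed.
#' @param outDir output directory (created if missing).
#' @param height,width,lesionContrast,noiseSigma,blurSigma phantom
#'   parameters shared by all images (see [PhantomSpec()]).
#' @return Invisibly, the manifest data.frame.
#' @export
generateDataset <- function(nPerClass, baseSeed, outDir,
                            height = 224L, width = 224L,
                            lesionContrast = 0.35, noiseSigma = 0.05,
                            blurSigma = 1.2) {
    stopifnot(nPerClass >= 1L)
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory ", outDir)
    labels <- rep(.phantom_labels, each = nPerClass)
    rows <- vector("list", length(labels))
    for (i in seq_along(labels)) {
        seed <- as.integer(baseSeed + i)
        spec <- PhantomSpec(labels[i], height, width, lesionContrast,
                            noiseSigma, blurSigma, seed)
        ph <- generatePhantom(spec)
        path <- file.path(outDir, sprintf("phantom_%04d_%s.png", i,
                                          labels[i]))
        writeImage(ph$image, path)
        maskPath <- ""
        if (labels[i] != "NP") {
            maskPath <- file.path(outDir,
                                  sprintf("phantom_%04d_%s_mask.png", i,
                                          labels[i]))
            png::writePNG(ph$mask * 1, maskPath)
        }
        rows[[i]] <- data.frame(path = path, label = labels[i], seed = seed,
                                lesion_contrast = lesionContrast,
                                mask_path = maskPath,
                                stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
    invisible(manifest)
}

#' Lesion contrast-to-noise score
#'
#' A CNR-style conspicuity score: the absolute difference between the mean
#' intensity over the lesion mask and over a surrounding background ring
#' (the 5-pixel dilation of the mask minus the mask itself), divided by
#' the background ring's standard deviation (+ 1e-6). Non-negative, and
#' invariant under intensity inversion of the image.
#'
#' @param img a [GrayImage-class].
#' @param mask logical matrix of lesion pixels (same shape as `img`); must
#'   contain at least one lesion pixel.
#' @param ringRadius dilation radius in pixels defining the background
#'   ring (default 5).
#' @return A non-negative number.
#' @export
lesionContrastMetric <- function(img, mask, ringRadius = 5L) {
    stopifnot(is(img, "GrayImage"), is.logical(mask),
              all(dim(mask) == dim(img)))
    if (!any(mask))
        stop("empty lesion mask (no-pathology input has no lesion score)")
    ring <- dilateMask(mask, ringRadius) & !mask
    if (!any(ring))
        stop("lesion mask has no background ring")
    v <- img@pixels
    abs(mean(v[mask]) - mean(v[ring])) / (sd(v[ring]) + 1e-6)
}

#' Pixel-statistics features of a phantom
#'
#' A small, label-agnostic feature vector used by the reference logistic
#' classifier that validates class separability: global mean/sd and
#' quantiles, plus mean, spread, low-tail quantiles and a high-pass
#' "mottling" score over the two fixed anatomical zones where lesions
#' occur (the bowel region and the sub-diaphragmatic band).
#'
#' @param img a [GrayImage-class].
#' @return A named numeric vector.
#' @export
phantomFeatures <- function(img) {
    stopifnot(is(img, "GrayImage"))
    v <- img@pixels
    z <- phantomZones(nrow(v), ncol(v))
    hp <- v - gaussianBlurMat(v, 2)
    bw <- v[z$bowel]; bd <- v[z$band]
    c(mean = mean(v), sd = sd(v),
      q10 = quantile(v, 0.10, names = FALSE),
      q50 = quantile(v, 0.50, names = FALSE),
      q90 = quantile(v, 0.90, names = FALSE),
      bowelMean = mean(bw), bowelSd = sd(bw),
      bowelQ05 = quantile(bw, 0.05, names = FALSE),
      bowelQ15 = quantile(bw, 0.15, names = FALSE),
      bowelMottle = sd(hp[z$bowel]),
      bandMean = mean(bd), bandSd = sd(bd),
      bandQ05 = quantile(bd, 0.05, names = FALSE),
      bandQ15 = quantile(bd, 0.15, names = FALSE),
      bandMottle = sd(hp[z$band]))
}
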