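#' @import methods
#' @importFrom stats rnorm runif quantile sd var pt
#' @importFrom utils read.csv write.csv
#' @importFrom tools file_ext
#' @importFrom Rcpp evalCpp
#' @useDynLib necaxr, .registration = TRUE
NULL

#' GrayImage: a single-channel intensity raster
#'
#' The universal currency of all operators in this package: a 2-D matrix of
#' finite real intensities in \[0, 1\], row-major with origin at the top-left
#' (row 1, column 1 is the top-left pixel; higher value = brighter tissue).
#' Rasters smaller than 8x8 are rejected because the neighbourhood operators
#' assume non-degenerate images.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @seealso [GrayImage()], [MultiChannelImage-class]
#' @exportClass GrayImage
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
    p <- object@pixels
    if (!is.numeric(p))
        return("pixels must be a numeric matrix")
    if (nrow(p) < 8L || ncol(p) < 8L)
        return("image must be at least 8x8 pixels")
    if (any(!is.finite(p)))
        return("all intensities must be finite")
    if (min(p) < 0 || max(p) > 1)
        return("intensities must lie in [0, 1]")
    TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix with values in \[0, 1\], at least 8x8.
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
GrayImage <- function(pixels) {
    new("GrayImage", pixels = pixels)
}

#' MultiChannelImage: an ordered stack of three aligned channels
#'
#' Exactly three [GrayImage-class] planes of identical shape. Channel order
#' is semantically fixed by the producing pipeline (see [pr2()]): consumers
#' must not reorder channels.
#'
#' @slot channels list of exactly 3 GrayImage objects of identical shape.
#' @seealso [toThreeChannel()], [pr1()], [pr2()]
#' @exportClass MultiChannelImage
setClass("MultiChannelImage", representation(channels = "list"))

setValidity("MultiChannelImage", function(object) {
    ch <- object@channels
    if (length(ch) != 3L)
        return("a MultiChannelImage has exactly 3 channels")
    if (!all(vapply(ch, is, logical(1), class2 = "GrayImage")))
        return("all channels must be GrayImage objects")
    dims <- vapply(ch, function(c) dim(c@pixels), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        return("all channels must share height and width")
    TRUE
})

#' Construct a MultiChannelImage
#'
#' @param channels list of exactly three [GrayImage-class] objects sharing
#'   height and width.
#' @return A [MultiChannelImage-class] object.
#' @export
MultiChannelImage <- function(channels) {
    new("MultiChannelImage", channels = channels)
}

#' AugmentSpec: one stochastic augmentation
#'
#' Names one augmentation, the per-draw chance that it is applied, and its
#' magnitude. Magnitude semantics depend on the augmentation:
#' \describe{
#'   \item{translation}{maximum shift as a fraction of image length, in
#'     \[0, 0.5\].}
#'   \item{cropping}{crop window side in pixels.}
#'   \item{rotation}{maximum rotation angle in degrees.}
#'   \item{occlusion}{occluded fraction of the image area, in (0, 1).}
#'   \item{noise}{Gaussian noise standard deviation on the \[0, 1\] scale.}
#'   \item{hflip, vflip, equalisation, sharpening, inversion}{no magnitude
#'     (ignored).}
#' }
#'
#' @slot name character, one of `translation`, `cropping`, `rotation`,
#'   `hflip`, `vflip`, `occlusion`, `noise`, `equalisation`, `sharpening`,
#'   `inversion`.
#' @slot chance numeric in \[0, 1\]: per-draw application probability.
#' @slot magnitude numeric magnitude (see above), `NA` where not applicable.
#' @exportClass AugmentSpec
setClass("AugmentSpec",
    representation(name = "character", chance = "numeric",
                   magnitude = "numeric"))

.augment_names <- c("translation", "cropping", "rotation", "hflip", "vflip",
                    "occlusion", "noise", "equalisation", "sharpening",
                    "inversion")

setValidity("AugmentSpec", function(object) {
    if (length(object@name) != 1L || !(object@name %in% .augment_names))
        return(paste0("unknown augmentation name; must be one of: ",
                      paste(.augment_names, collapse = ", ")))
    if (length(object@chance) != 1L || is.na(object@chance) ||
        object@chance < 0 || object@chance > 1)
        return("chance must be a single value in [0, 1]")
    m <- object@magnitude
    ok <- switch(object@name,
        translation = !is.na(m) && m >= 0 && m <= 0.5,
        cropping    = !is.na(m) && m >= 1,
        rotation    = !is.na(m) && m >= 0,
        occlusion   = !is.na(m) && m > 0 && m < 1,
        noise       = !is.na(m) && m > 0,
        TRUE)
    if (!isTRUE(ok))
        return(sprintf("magnitude %g out of range for '%s'", m, object@name))
    TRUE
})

#' Construct an AugmentSpec
#'
#' @param name augmentation name (see [AugmentSpec-class]).
#' @param chance application probability in \[0, 1\].
#' @param magnitude operator-specific magnitude; defaults per augmentation
#'   follow the study settings (translation 0.10, cropping 159, rotation 20,
#'   occlusion 0.05, noise 0.05).
#' @return An [AugmentSpec-class] object.
#' @examples
#' AugmentSpec("translation", chance = 1, magnitude = 0.10)
#' @export
AugmentSpec <- function(name, chance, magnitude = NULL) {
    if (is.null(magnitude)) {
        magnitude <- switch(name,
            translation = 0.10, cropping = 159, rotation = 20,
            occlusion = 0.05, noise = 0.05, NA_real_)
    }
    new("AugmentSpec", name = name, chance = as.numeric(chance),
        magnitude = as.numeric(magnitude))
}

#' AugmentPolicy: an ordered list of augmentations with a seed
#'
#' Applying the policy twice with the same seed and input yields identical
#' outputs; see [applyPolicy()].
#'
#' @slot specs list of [AugmentSpec-class] objects, applied in order.
#' @slot seed integer RNG seed.
#' @exportClass AugmentPolicy
setClass("AugmentPolicy",
    representation(specs = "list", seed = "integer"))

setValidity("AugmentPolicy", function(object) {
    if (!all(vapply(object@specs, is, logical(1), class2 = "AugmentSpec")))
        return("specs must all be AugmentSpec objects")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed must be a single integer")
    TRUE
})

#' Construct an AugmentPolicy
#'
#' @param specs list of [AugmentSpec-class] objects (order matters).
#' @param seed integer seed making the policy reproducible.
#' @return An [AugmentPolicy-class] object.
#' @examples
#' pol <- AugmentPolicy(list(AugmentSpec("translation", 1, 0.10)), seed = 1)
#' @export
AugmentPolicy <- function(specs, seed = 0L) {
    new("AugmentPolicy", specs = specs, seed = as.integer(seed))
}

#' PhantomSpec: parameters of one synthetic radiograph
#'
#' Fully determines one phantom: the image produced by [generatePhantom()]
#' is a deterministic function of the spec (including its seed).
#'
#' @slot label character, one of `NP`, `mNEC`, `sNEC`.
#' @slot height,width integer raster size in pixels.
#' @slot lesionContrast numeric in \[0, 1\]: intensity offset of
#'   class-specific lesions relative to their surroundings (0 = invisible).
#' @slot noiseSigma numeric in \[0, 1\]: additive Gaussian noise sd.
#' @slot blurSigma positive numeric: system blur in pixels.
#' @slot seed integer per-image seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(label = "character", height = "integer", width = "integer",
                   lesionContrast = "numeric", noiseSigma = "numeric",
                   blurSigma = "numeric", seed = "integer"))

.phantom_labels <- c("NP", "mNEC", "sNEC")

setValidity("PhantomSpec", function(object) {
    if (!(object@label %in% .phantom_labels))
        return("label must be one of NP, mNEC, sNEC")
    if (object@height < 32L || object@width < 32L)
        return("phantoms need at least 32x32 pixels of anatomy")
    if (object@lesionContrast < 0 || object@lesionContrast > 1)
        return("lesionContrast must lie in [0, 1]")
    if (object@noiseSigma < 0 || object@noiseSigma > 1)
        return("noiseSigma must lie in [0, 1]")
    if (object@blurSigma <= 0)
        return("blurSigma must be positive")
    TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate the subtlety of the clinical problem: a 224x224 frame,
#' lesions at contrast 0.35 (faint against the bowel background), moderate
#' noise and mild system blur.
#'
#' @param label class label: `"NP"`, `"mNEC"` or `"sNEC"`.
#' @param height,width raster size in pixels (default 224).
#' @param lesionContrast lesion intensity offset in \[0, 1\] (default 0.35).
#' @param noiseSigma additive Gaussian noise sd (default 0.05).
#' @param blurSigma Gaussian system blur in pixels (default 1.2).
#' @param seed integer seed (default 0).
#' @return A [PhantomSpec-class] object.
#' @examples
#' sp <- PhantomSpec("mNEC", seed = 7)
#' ph <- generatePhantom(sp)
#' @export
PhantomSpec <- function(label, height = 224L, width = 224L,
                        lesionContrast = 0.35, noiseSigma = 0.05,
                        blurSigma = 1.2, seed = 0L) {
    new("PhantomSpec", label = label, height = as.integer(height),
        width = as.integer(width), lesionContrast = lesionContrast,
        noiseSigma = noiseSigma, blurSigma = blurSigma,
        seed = as.integer(seed))
}

#' FoldSplit: a stratified k-fold assignment
#'
#' @slot k integer number of folds.
#' @slot assignments integer vector of fold indices in \[1, k\], named by
#'   image id; every image appears in exactly one fold and per-label counts
#'   across folds differ by at most one.
#' @slot labels character vector of class labels, parallel to assignments.
#' @seealso [makeFolds()]
#' @exportClass FoldSplit
setClass("FoldSplit",
    representation(k = "integer", assignments = "integer",
                   labels = "character"))

setValidity("FoldSplit", function(object) {
    if (object@k < 2L)
        return("k must be at least 2")
    if (length(object@assignments) != length(object@labels))
        return("assignments and labels must be parallel")
    if (any(object@assignments < 1L | object@assignments > object@k))
        return("fold indices must lie in [1, k]")
    for (lab in unique(object@labels)) {
        cnt <- tabulate(object@assignments[object@labels == lab], object@k)
        if (max(cnt) - min(cnt) > 1L)
            return(sprintf("folds are not stratified for label %s", lab))
    }
    TRUE
})

#' MetricsReport: per-fold and aggregate classification metrics
#'
#' Accuracy, macro-averaged precision, recall and F1 per cross-validation
#' fold, with mean and standard deviation across folds, plus a fingerprint
#' of the configuration that produced them.
#'
#' @slot perFold data.frame with columns fold, accuracy, precision, recall,
#'   f1 (one row per fold, each metric in \[0, 1\]).
#' @slot fingerprint named list describing the run (pipeline, policy names,
#'   seed, backbone settings).
#' @seealso [trainEval()], [compareRuns()]
#' @exportClass MetricsReport
setClass("MetricsReport",
    representation(perFold = "data.frame", fingerprint = "list"))

setValidity("MetricsReport", function(object) {
    pf <- object@perFold
    need <- c("fold", "accuracy", "precision", "recall", "f1")
    if (!all(need %in% names(pf)))
        return("perFold must have columns fold, accuracy, precision, recall, f1")
    vals <- unlist(pf[c("accuracy", "precision", "recall", "f1")])
    if (length(vals) && (min(vals) < 0 || max(vals) > 1))
        return("all metrics must lie in [0, 1]")
    TRUE
})
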