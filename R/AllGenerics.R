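#' Accessors for image classes
#'
#' `pixels()` returns the intensity matrix of a [GrayImage-class];
#' `channels()` the list of planes of a [MultiChannelImage-class];
#' `getChannel()` one plane as a GrayImage.
#'
#' @param x a GrayImage or MultiChannelImage.
#' @param i channel index in 1..3.
#' @return `pixels()`: a numeric matrix. `channels()`: a list of three
#'   GrayImage objects. `getChannel()`: a GrayImage.
#' @examples
#' img <- GrayImage(matrix(0.5, 8, 8))
#' range(pixels(img))
#' @name image-accessors
NULL

#' @rdname image-accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname image-accessors
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname image-accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname image-accessors
#' @export
setMethod("channels", "MultiChannelImage", function(x) x@channels)

#' @rdname image-accessors
#' @export
setGeneric("getChannel", function(x, i) standardGeneric("getChannel"))

#' @rdname image-accessors
#' @export
setMethod("getChannel", "MultiChannelImage", function(x, i) {
    stopifnot(i >= 1L, i <= 3L)
    x@channels[[i]]
})

#' @describeIn GrayImage-class image dimensions, `c(height, width)`.
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn MultiChannelImage-class per-channel dimensions,
#'   `c(height, width)`.
#' @param x a MultiChannelImage.
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@channels[[1]]@pixels))

setMethod("show", "GrayImage", function(object) {
    p <- object@pixels
    cat(sprintf("GrayImage %dx%d, range [%.4f, %.4f], mean %.4f\n",
                nrow(p), ncol(p), min(p), max(p), mean(p)))
})

setMethod("show", "MultiChannelImage", function(object) {
    d <- dim(object)
    cat(sprintf("MultiChannelImage %dx%dx3\n", d[1], d[2]))
    for (i in 1:3) {
        p <- object@channels[[i]]@pixels
        cat(sprintf("  channel %d: range [%.4f, %.4f], mean %.4f\n",
                    i - 1L, min(p), max(p), mean(p)))
    }
})

setMethod("show", "AugmentSpec", function(object) {
    cat(sprintf("AugmentSpec '%s': chance %.2f, magnitude %s\n",
                object@name, object@chance,
                ifelse(is.na(object@magnitude), "-",
                       format(object@magnitude))))
})

setMethod("show", "AugmentPolicy", function(object) {
    cat(sprintf("AugmentPolicy (%d specs, seed %d)\n",
                length(object@specs), object@seed))
    for (s in object@specs)
        cat("  -", s@name, sprintf("C=%.2f", s@chance),
            if (!is.na(s@magnitude)) sprintf("mag=%g", s@magnitude) else "",
            "\n")
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec %s %dx%d (contrast %.2f, noise %.3f, blur %.2f, seed %d)\n",
        object@label, object@height, object@width, object@lesionContrast,
        object@noiseSigma, object@blurSigma, object@seed))
})

setMethod("show", "FoldSplit", function(object) {
    cat(sprintf("FoldSplit: %d images in %d stratified folds\n",
                length(object@assignments), object@k))
    print(table(label = object@labels, fold = object@assignments))
})

setMethod("show", "MetricsReport", function(object) {
    cat("MetricsReport\n")
    print(object@perFold, row.names = FALSE, digits = 4)
    s <- metricsSummary(object)
    cat(sprintf("mean accuracy %.4f +/- %.4f | macro F1 %.4f +/- %.4f\n",
                s["accuracy", "mean"], s["accuracy", "sd"],
                s["f1", "mean"], s["f1", "sd"]))
})

#' Accessors for fold splits and metrics reports
#'
#' @param x a [FoldSplit-class] or [MetricsReport-class].
#' @return `foldK()`: the number of folds. `foldAssignments()`: named
#'   integer vector of fold indices. `perFold()`: the per-fold metrics
#'   data.frame. `fingerprint()`: the run-configuration list.
#'   `metricsSummary()`: a data.frame with rows accuracy/precision/recall/f1
#'   and columns mean, sd.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("foldK", function(x) standardGeneric("foldK"))

#' @rdname report-accessors
#' @export
setMethod("foldK", "FoldSplit", function(x) x@k)

#' @rdname report-accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname report-accessors
#' @export
setMethod("foldAssignments", "FoldSplit", function(x) x@assignments)

#' @rdname report-accessors
#' @export
setGeneric("perFold", function(x) standardGeneric("perFold"))

#' @rdname report-accessors
#' @export
setMethod("perFold", "MetricsReport", function(x) x@perFold)

#' @rdname report-accessors
#' @export
setGeneric("fingerprint", function(x) standardGeneric("fingerprint"))

#' @rdname report-accessors
#' @export
setMethod("fingerprint", "MetricsReport", function(x) x@fingerprint)

#' @rdname report-accessors
#' @export
metricsSummary <- function(x) {
    stopifnot(is(x, "MetricsReport"))
    pf <- x@perFold
    out <- t(vapply(c("accuracy", "precision", "recall", "f1"),
                    function(m) c(mean = mean(pf[[m]]), sd = sd(pf[[m]])),
                    numeric(2)))
    as.data.frame(out)
}
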