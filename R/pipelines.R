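#' Preprocessing pipeline configuration
#'
#' Bundles the parameters of every operator used by the composed pipelines.
#' Defaults: Laplacian sharpening kernel, CLAHE with an 8x8 tile grid and
#' clip limit 2, percentile compression at 2/98, unsharp masking with
#' sigma 1 and amount 1, and edge-aware illumination enhancement with
#' alpha 0.15, gamma 0.8.
#'
#' @param kernel 3x3 sharpening kernel summing to 1 (see [sharpen()]).
#' @param claheP list from [claheParams()].
#' @param compress list with elements `lowPct`, `highPct` (see
#'   [compressHistogram()]).
#' @param unsharp list with elements `sigma`, `amount` (see
#'   [unsharpMask()]).
#' @param limeP list from [limeParams()].
#' @return A named list of validated pipeline parameters.
#' @seealso [pr1()], [pr2()], [runPipeline()]
#' @export
pipelineConfig <- function(kernel = sharpenKernel(),
                           claheP = claheParams(),
                           compress = list(lowPct = 2, highPct = 98),
                           unsharp = list(sigma = 1.0, amount = 1.0),
                           limeP = limeParams()) {
    stopifnot(abs(sum(kernel) - 1) <= 1e-9,
              compress$lowPct < compress$highPct,
              unsharp$sigma > 0, unsharp$amount >= 0)
    list(sharpenKernel = kernel, clahe = claheP,
         compress = compress, unsharp = unsharp, lime = limeP)
}

#' Pr-1: contrast-centred preprocessing
#'
#' Applies the two most effective intensity transforms deterministically
#' (with 100% likelihood): Laplacian sharpening followed by global
#' histogram equalisation, then replicates the result into three channels.
#' Sharpening runs first so that equalisation's output histogram is not
#' re-distorted.
#'
#' @param img a [GrayImage-class].
#' @param cfg a [pipelineConfig()] list.
#' @return A [MultiChannelImage-class] with three identical channels.
#' @export
pr1 <- function(img, cfg = pipelineConfig()) {
    stopifnot(is(img, "GrayImage"))
    toThreeChannel(histEqualize(sharpen(img, cfg$sharpenKernel)))
}

#' Pr-2: edge-centred three-channel preprocessing
#'
#' Stacks three differently enhanced versions of the input:
#' \describe{
#'   \item{channel 0}{Laplacian sharpening;}
#'   \item{channel 1}{sharpening followed by CLAHE for local contrast;}
#'   \item{channel 2}{percentile dynamic-range compression, then unsharp
#'     masking, then illumination-map low-light enhancement, emphasising
#'     edge-defining structures.}
#' }
#' All channels share the input's shape; the pipeline is deterministic.
#'
#' @param img a [GrayImage-class].
#' @param cfg a [pipelineConfig()] list.
#' @return A [MultiChannelImage-class].
#' @export
pr2 <- function(img, cfg = pipelineConfig()) {
    stopifnot(is(img, "GrayImage"))
    sh <- sharpen(img, cfg$sharpenKernel)
    ch0 <- sh
    ch1 <- clahe(sh, cfg$clahe)
    ch2 <- limeEnhance(
        unsharpMask(compressHistogram(img, cfg$compress$lowPct,
                                      cfg$compress$highPct),
                    cfg$unsharp$sigma, cfg$unsharp$amount),
        cfg$lime)
    MultiChannelImage(list(ch0, ch1, ch2))
}

#' Dispatch a named preprocessing pipeline
#'
#' `"baseline"` is pure channel replication; `"pr1"` and `"pr2"` dispatch
#' to [pr1()] and [pr2()].
#'
#' @param name one of `"baseline"`, `"pr1"`, `"pr2"`.
#' @param img a [GrayImage-class].
#' @param cfg a [pipelineConfig()] list.
#' @return A [MultiChannelImage-class].
#' @examples
#' img <- GrayImage(matrix(runif(256), 16, 16))
#' out <- runPipeline("pr1", img)
#' @export
runPipeline <- function(name, img, cfg = pipelineConfig()) {
    switch(name,
        baseline = toThreeChannel(img),
        pr1 = pr1(img, cfg),
        pr2 = pr2(img, cfg),
        stop("unknown pipeline '", name,
             "'; must be baseline, pr1 or pr2"))
}
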