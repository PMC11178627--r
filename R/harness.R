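#' Stratified k-fold assignment
#'
#' Shuffles each label's images under `seed` and deals them round-robin
#' into `k` folds, so per-label counts across folds differ by at most one
#' and every image appears in exactly one fold. With 320 images per label
#' and `k = 5` every fold holds exactly 64 images of each label.
#'
#' @param labels character vector of class labels (one per image), or a
#'   manifest data.frame with a `label` column.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A [FoldSplit-class].
#' @examples
#' fs <- makeFolds(rep(c("NP", "mNEC", "sNEC"), each = 5), k = 5, seed = 1)
#' foldAssignments(fs)
#' @export
makeFolds <- function(labels, k = 5L, seed = 0L) {
    if (is.data.frame(labels)) labels <- labels$label
    labels <- as.character(labels)
    k <- as.integer(k)
    counts <- table(labels)
    if (any(counts < k))
        stop("every label needs at least k images; short: ",
             paste(names(counts)[counts < k], collapse = ", "))
    assignments <- integer(length(labels))
    labSeeds <- deriveSeeds(seed, length(counts))
    for (i in seq_along(counts)) {
        lab <- names(counts)[i]
        idx <- which(labels == lab)
        ord <- withSeed(labSeeds[i], sample(idx))
        assignments[ord] <- rep_len(seq_len(k), length(ord))
    }
    names(assignments) <- if (!is.null(names(labels))) names(labels)
                          else as.character(seq_along(labels))
    new("FoldSplit", k = k, assignments = assignments, labels = labels)
}

#' Classification metrics for a three-class task
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the class
#' set: per-class precision/recall substitute 0 when a class receives no
#' predictions (or has no instances), per-class F1 is the harmonic mean,
#' and macro values are the unweighted means over classes.
#'
#' @param yTrue,yPred label vectors of equal length (character or factor).
#' @param classes the class set; defaults to the union of observed labels.
#' @return Named numeric vector `c(accuracy, precision, recall, f1)`.
#' @examples
#' computeMetrics(c("NP", "mNEC"), c("NP", "mNEC"))
#' @export
computeMetrics <- function(yTrue, yPred,
                           classes = sort(unique(c(as.character(yTrue),
                                                   as.character(yPred))))) {
    yTrue <- as.character(yTrue); yPred <- as.character(yPred)
    if (length(yTrue) != length(yPred) || length(yTrue) < 1L)
        stop("yTrue and yPred must have equal positive length")
    acc <- mean(yTrue == yPred)
    prec <- rec <- f1 <- numeric(length(classes))
    for (i in seq_along(classes)) {
        cl <- classes[i]
        tp <- sum(yTrue == cl & yPred == cl)
        predN <- sum(yPred == cl)
        trueN <- sum(yTrue == cl)
        prec[i] <- if (predN > 0) tp / predN else 0
        rec[i] <- if (trueN > 0) tp / trueN else 0
        f1[i] <- if (prec[i] + rec[i] > 0)
            2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    }
    c(accuracy = acc, precision = mean(prec), recall = mean(rec),
      f1 = mean(f1))
}

#' Training configuration for the evaluation harness
#'
#' @param pipeline preprocessing pipeline name: `"baseline"`, `"pr1"` or
#'   `"pr2"`.
#' @param policy an [AugmentPolicy-class] applied per image per epoch
#'   during training, or `NULL` for none.
#' @param backbone `"small_cnn"` (default; four conv blocks, see
#'   [cnnFit()]) or `"mlp"` (one-hidden-layer softmax network on
#'   flattened pixels, see [netFit()]).
#' @param hidden hidden width of the mlp backbone (default 32).
#' @param learningRate Adam learning rate (default 0.003, suited to a
#'   small backbone trained from scratch).
#' @param batchSize minibatch size (default 16).
#' @param epochs training epochs (default 50).
#' @param trainSize side of the square training resolution the images are
#'   resized to before preprocessing (default 32; must be divisible by 16
#'   for the cnn backbone).
#' @param seed integer seed driving fold-wise weight init, shuffling and
#'   augmentation draws.
#' @param cfg a [pipelineConfig()] list.
#' @return A named list of validated settings.
#' @export
trainConfig <- function(pipeline = "baseline", policy = NULL,
                        backbone = c("small_cnn", "mlp"),
                        hidden = 32L, learningRate = 0.003,
                        batchSize = 16L, epochs = 50L, trainSize = 32L,
                        seed = 0L, cfg = pipelineConfig()) {
    backbone <- match.arg(backbone)
    stopifnot(pipeline %in% c("baseline", "pr1", "pr2"),
              is.null(policy) || is(policy, "AugmentPolicy"),
              learningRate > 0, batchSize >= 1L, epochs >= 1L,
              trainSize >= 16L)
    if (backbone == "small_cnn" && trainSize %% 16L != 0L)
        stop("trainSize must be divisible by 16 for the small_cnn backbone")
    list(pipeline = pipeline, policy = policy, backbone = backbone,
         hidden = as.integer(hidden),
         learningRate = learningRate, batchSize = as.integer(batchSize),
         epochs = as.integer(epochs), trainSize = as.integer(trainSize),
         seed = as.integer(seed), cfg = cfg)
}

# Resize to the working (training) resolution with an anti-aliased
# downsample, then run the configured pipeline at that resolution:
# preprocessing operates on the raster the classifier actually sees.
.prepChannels <- function(img, config) {
    s <- config$trainSize
    small <- GrayImage(clip01(antialiasResize(img@pixels, s, s)))
    mci <- runPipeline(config$pipeline, small, config$cfg)
    lapply(mci@channels, function(ch) ch@pixels)
}

.flattenChannels <- function(chl) {
    unlist(lapply(chl, as.vector), use.names = FALSE)
}

#' Cross-validated training and evaluation
#'
#' Replicates the evaluation protocol at desk scale: images are resized
#' (anti-aliased bilinear) to the training resolution, preprocessed with
#' the configured pipeline (cached, since preprocessing is deterministic
#' per image), then for each fold the held-in images are augmented per
#' image per epoch with the configured policy (one draw plan per
#' image-epoch, replayed across the three channels) and used to train the
#' configured backbone with Adam and multiclass cross-entropy. The
#' held-out fold is classified by argmax over the predicted class
#' probabilities.
#'
#' @param images list of [GrayImage-class] objects, or a manifest
#'   data.frame with `path` and `label` columns (images are read from
#'   disk).
#' @param labels character vector of class labels (ignored when `images`
#'   is a manifest).
#' @param folds a [FoldSplit-class] over the same images.
#' @param config a [trainConfig()] list.
#' @return A [MetricsReport-class].
#' @export
trainEval <- function(images, labels = NULL, folds, config = trainConfig()) {
    if (is.data.frame(images)) {
        labels <- as.character(images$label)
        images <- lapply(images$path, readGrayImage)
    }
    stopifnot(length(images) == length(labels),
              is(folds, "FoldSplit"),
              length(labels) == length(folds@assignments))
    classes <- sort(unique(labels))
    yAll <- factor(labels, levels = classes)
    prep <- lapply(images, .prepChannels, config = config)
    s <- config$trainSize
    n <- length(prep)
    # full input tensor [s, s, 3, n] in [0, 1]
    Xall <- array(0, c(s, s, 3L, n))
    for (i in seq_len(n))
        for (ch in 1:3) Xall[, , ch, i] <- prep[[i]][[ch]]
    assign <- folds@assignments
    foldSeeds <- deriveSeeds(config$seed, folds@k)
    perFold <- vector("list", folds@k)
    for (f in seq_len(folds@k)) {
        trIdx <- which(assign != f)
        teIdx <- which(assign == f)
        # per-channel standardisation fitted on the training fold
        mu <- vapply(1:3, function(ch) mean(Xall[, , ch, trIdx]), numeric(1))
        sg <- pmax(vapply(1:3, function(ch) sd(Xall[, , ch, trIdx]),
                          numeric(1)), 1e-6)
        std <- function(X) {
            for (ch in 1:3) X[, , ch, ] <- (X[, , ch, ] - mu[ch]) / sg[ch]
            X
        }
        Xtr <- std(Xall[, , , trIdx, drop = FALSE])
        Xte <- std(Xall[, , , teIdx, drop = FALSE])
        hook <- NULL
        if (!is.null(config$policy)) {
            augSeeds <- deriveSeeds(foldSeeds[f] + 7L,
                                    config$epochs * length(trIdx))
            hook <- function(ep) {
                Xa <- array(0, c(s, s, 3L, length(trIdx)))
                for (j in seq_along(trIdx)) {
                    chl <- prep[[trIdx[j]]]
                    sd_ <- augSeeds[(ep - 1L) * length(trIdx) + j]
                    mci <- MultiChannelImage(lapply(chl, GrayImage))
                    aug <- applyPolicyMulti(mci, config$policy, seed = sd_)
                    for (ch in 1:3)
                        Xa[, , ch, j] <- aug@channels[[ch]]@pixels
                }
                std(Xa)
            }
        }
        ytr <- droplevels(yAll[trIdx])
        if (config$backbone == "small_cnn") {
            model <- cnnFit(Xtr, ytr, lr = config$learningRate,
                            batchSize = config$batchSize,
                            epochs = config$epochs, seed = foldSeeds[f],
                            epochHook = hook)
            pred <- cnnPredict(model, Xte, type = "class")
        } else {
            flat <- function(X) t(apply(X, 4, as.vector))
            mlpHook <- if (is.null(hook)) NULL else function(ep) flat(hook(ep))
            model <- netFit(flat(Xtr), ytr, hidden = config$hidden,
                            lr = config$learningRate,
                            batchSize = config$batchSize,
                            epochs = config$epochs, seed = foldSeeds[f],
                            epochHook = mlpHook)
            pred <- netPredict(model, flat(Xte), type = "class")
        }
        m <- computeMetrics(yAll[teIdx], pred, classes = classes)
        perFold[[f]] <- data.frame(fold = f, accuracy = m["accuracy"],
                                   precision = m["precision"],
                                   recall = m["recall"], f1 = m["f1"],
                                   row.names = NULL)
    }
    new("MetricsReport",
        perFold = do.call(rbind, perFold),
        fingerprint = list(
            pipeline = config$pipeline,
            policy = if (is.null(config$policy)) character(0)
                     else vapply(config$policy@specs, slot, character(1),
                                 "name"),
            backbone = config$backbone,
            learningRate = config$learningRate,
            batchSize = config$batchSize, epochs = config$epochs,
            trainSize = config$trainSize, seed = config$seed,
            k = folds@k))
}

#' Compare runs against a baseline
#'
#' For each non-baseline report: the difference in mean per-fold accuracy
#' against the baseline report and a two-sided Welch t-test p-value over
#' the per-fold accuracies (fold variances floored at 1e-12 so
#' zero-variance folds still yield a decision; identical means give
#' p = 1). All reports must come from the same fold split.
#'
#' @param reports named list of [MetricsReport-class] objects.
#' @param baseline name or index of the baseline report (default 1).
#' @return A data.frame with columns `name`, `meanAccuracy`,
#'   `deltaAccuracy`, `pValue`, one row per non-baseline report.
#' @export
compareRuns <- function(reports, baseline = 1L) {
    stopifnot(length(reports) >= 1L,
              all(vapply(reports, is, logical(1), class2 = "MetricsReport")))
    ks <- vapply(reports, function(r) nrow(r@perFold), integer(1))
    if (length(unique(ks)) != 1L)
        stop("all reports must share the same fold split")
    bIdx <- if (is.character(baseline)) match(baseline, names(reports))
            else as.integer(baseline)
    if (is.na(bIdx) || bIdx < 1L || bIdx > length(reports))
        stop("baseline report not found")
    accB <- reports[[bIdx]]@perFold$accuracy
    others <- setdiff(seq_along(reports), bIdx)
    rows <- lapply(others, function(i) {
        acc <- reports[[i]]@perFold$accuracy
        delta <- mean(acc) - mean(accB)
        p <- .welchP(acc, accB)
        data.frame(name = if (!is.null(names(reports))) names(reports)[i]
                          else as.character(i),
                   meanAccuracy = mean(acc), deltaAccuracy = delta,
                   pValue = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

# Welch t-test with variances floored to keep zero-variance folds decidable.
.welchP <- function(a, b, floorVar = 1e-12) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    va <- max(var(a), floorVar); vb <- max(var(b), floorVar)
    na <- length(a); nb <- length(b)
    se2 <- va / na + vb / nb
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    2 * pt(-abs(tstat), df)
}
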