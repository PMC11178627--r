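# A small convolutional network: four 3x3 conv + ReLU + 2x2 mean-pool
# blocks, global average pooling, softmax head, trained with Adam on
# multiclass cross-entropy. Convolutions run as im2col (compiled,
# src/conv3x3.cpp) + BLAS matrix products; the batch lives in an
# [h, w, n, c] array (channel-last keeps every reshape a free `dim<-`).

.meanPool2 <- function(X) {
    d <- dim(X)
    oi <- seq(1, d[1], by = 2); oj <- seq(1, d[2], by = 2)
    (X[oi, oj, , , drop = FALSE] + X[oi + 1, oj, , , drop = FALSE] +
     X[oi, oj + 1, , , drop = FALSE] + X[oi + 1, oj + 1, , , drop = FALSE]) / 4
}

.meanPool2Back <- function(dY, h, w) {
    d <- dim(dY)
    dX <- array(0, c(h, w, d[3], d[4]))
    oi <- seq(1, h, by = 2); oj <- seq(1, w, by = 2)
    g <- dY / 4
    dX[oi, oj, , ] <- g; dX[oi + 1, oj, , ] <- g
    dX[oi, oj + 1, , ] <- g; dX[oi + 1, oj + 1, , ] <- g
    dX
}

.cnnForward <- function(X, w, keepCache = FALSE) {
    cache <- list()
    A <- X                                   # [h, w, n, c]
    for (l in seq_along(w$conv)) {
        d <- dim(A)
        M <- im2col3(A, d[1], d[2], d[3], d[4])
        Z <- M %*% w$conv[[l]]$W
        Z <- Z + rep(w$conv[[l]]$b, each = nrow(Z))
        P <- reluPool2(Z, d[1], d[2], d[3])
        if (keepCache) cache[[l]] <- list(M = M, Z = Z, dIn = d)
        A <- P
    }
    d <- dim(A)
    feat <- matrix(colMeans(matrix(A, d[1] * d[2], d[3] * d[4])), d[3], d[4])
    z <- sweep(feat %*% w$head$W, 2, w$head$b, `+`)
    list(probs = .softmax(z), feat = feat, cache = cache, dTop = d)
}

.cnnGrads <- function(w, Xb, Yb) {
    m <- dim(Xb)[3]
    fw <- .cnnForward(Xb, w, keepCache = TRUE)
    dz <- (fw$probs - Yb) / m
    grads <- list(Wh = t(fw$feat) %*% dz, bh = colSums(dz))
    dFeat <- dz %*% t(w$head$W)              # [n, fTop]
    dTop <- fw$dTop
    dA <- array(rep(as.vector(dFeat) / (dTop[1] * dTop[2]),
                    each = dTop[1] * dTop[2]), dTop)
    for (l in rev(seq_along(w$conv))) {
        cc <- fw$cache[[l]]
        dZ <- reluPool2Bwd(dA, cc$Z, cc$dIn[1], cc$dIn[2], cc$dIn[3])
        grads[[paste0("W", l)]] <- crossprod(cc$M, dZ)
        grads[[paste0("b", l)]] <- colSums(dZ)
        if (l > 1L) {
            dM <- tcrossprod(dZ, w$conv[[l]]$W)
            dA <- col2im3(dM, cc$dIn[1], cc$dIn[2], cc$dIn[3], cc$dIn[4])
        }
    }
    grads
}

#' Fit a small convolutional network
#'
#' Four blocks of 3x3 convolution (zero padding), ReLU and 2x2 mean
#' pooling, followed by global average pooling and a softmax head,
#' trained with the Adam optimiser on multiclass cross-entropy in
#' shuffled minibatches. Weight initialisation, shuffling and per-epoch
#' input regeneration are deterministic functions of `seed`.
#'
#' @param X numeric array `[h, w, channels, n]`; `h` and `w` must be
#'   divisible by 16 (four pooling stages).
#' @param y factor of class labels (length `n`).
#' @param filters integer vector of filter counts for the four blocks.
#' @param lr Adam learning rate (default 0.003, suited to training from
#'   scratch).
#' @param batchSize minibatch size (default 16).
#' @param epochs training epochs (default 40).
#' @param seed integer seed.
#' @param epochHook optional `function(epoch)` returning the input array
#'   (same shape as `X`) for that epoch, enabling per-epoch augmentation.
#' @return An object of class `necaxrCNN`.
#' @seealso [cnnPredict()], [netFit()]
#' @export
cnnFit <- function(X, y, filters = c(8L, 16L, 32L, 32L), lr = 0.003,
                   batchSize = 16L, epochs = 40L, seed = 0L,
                   epochHook = NULL) {
    d <- dim(X)
    stopifnot(length(d) == 4L, is.factor(y), d[4] == length(y),
              d[1] %% 16L == 0L, d[2] %% 16L == 0L,
              lr > 0, batchSize >= 1L, epochs >= 1L)
    n <- d[4]; k <- nlevels(y)
    Y <- diag(k)[as.integer(y), , drop = FALSE]
    inCh <- c(d[3], filters[-length(filters)])
    w <- withSeed(seed, {
        conv <- lapply(seq_along(filters), function(l) {
            fanIn <- 9L * inCh[l]
            list(W = matrix(rnorm(fanIn * filters[l], 0, sqrt(2 / fanIn)),
                            fanIn, filters[l]),
                 b = rep(0, filters[l]))
        })
        fTop <- filters[length(filters)]
        list(conv = conv,
             head = list(W = matrix(rnorm(fTop * k, 0, sqrt(2 / fTop)),
                                    fTop, k),
                         b = rep(0, k)))
    })
    flat <- .cnnFlatten(w)
    state <- list(w = flat, m = lapply(flat, function(x) x * 0),
                  v = lapply(flat, function(x) x * 0), t = 0L)
    orderSeeds <- deriveSeeds(seed + 1L, epochs)
    for (ep in seq_len(epochs)) {
        Xe <- aperm(if (is.null(epochHook)) X else epochHook(ep),
                    c(1, 2, 4, 3))
        ord <- withSeed(orderSeeds[ep], sample.int(n))
        for (start in seq(1L, n, by = batchSize)) {
            idx <- ord[start:min(start + batchSize - 1L, n)]
            grads <- .cnnGrads(.cnnUnflatten(state$w, length(filters)),
                               Xe[, , idx, , drop = FALSE],
                               Y[idx, , drop = FALSE])
            if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1))))
                stop("non-finite loss gradient during training")
            state <- .adamStep(state, grads, lr)
        }
    }
    structure(list(w = .cnnUnflatten(state$w, length(filters)),
                   filters = filters, levels = levels(y),
                   inDim = d[1:3]),
              class = "necaxrCNN")
}

.cnnFlatten <- function(w) {
    out <- list()
    for (l in seq_along(w$conv)) {
        out[[paste0("W", l)]] <- w$conv[[l]]$W
        out[[paste0("b", l)]] <- w$conv[[l]]$b
    }
    out$Wh <- w$head$W; out$bh <- w$head$b
    out
}

.cnnUnflatten <- function(flat, nconv) {
    list(conv = lapply(seq_len(nconv), function(l)
             list(W = flat[[paste0("W", l)]], b = flat[[paste0("b", l)]])),
         head = list(W = flat$Wh, b = flat$bh))
}

#' Predict class probabilities from a fitted convolutional network
#'
#' @param model a `necaxrCNN` from [cnnFit()].
#' @param X numeric array `[h, w, channels, n]`.
#' @param type `"prob"` for the probability matrix, `"class"` for the
#'   argmax label.
#' @return A probability matrix or a factor of predicted labels.
#' @export
cnnPredict <- function(model, X, type = c("prob", "class")) {
    type <- match.arg(type)
    p <- .cnnForward(aperm(X, c(1, 2, 4, 3)), model$w)$probs
    colnames(p) <- model$levels
    if (type == "prob") return(p)
    factor(model$levels[max.col(p, ties.method = "first")],
           levels = model$levels)
}
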