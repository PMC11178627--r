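# A small fully-connected softmax network trained with Adam and
# multiclass cross-entropy: the desk-scale stand-in for a convolutional
# backbone. hidden = 0 gives plain multinomial logistic regression.

.softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
}

.adamStep <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    for (nm in names(grads)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        mhat <- state$m[[nm]] / (1 - beta1^state$t)
        vhat <- state$v[[nm]] / (1 - beta2^state$t)
        state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state
}

#' Fit a small softmax network
#'
#' One optional ReLU hidden layer followed by a softmax output, trained
#' with the Adam optimiser on multiclass cross-entropy in shuffled
#' minibatches. Fully seeded: weight initialisation, shuffling and (via
#' `epochHook`) per-epoch input regeneration are deterministic functions
#' of `seed`. With `hidden = 0` this is multinomial logistic regression.
#'
#' @param X numeric matrix, one row per example.
#' @param y factor of class labels (length `nrow(X)`).
#' @param hidden hidden layer width (0 for none; default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param batchSize minibatch size (default 16).
#' @param epochs training epochs (>= 1; default 30).
#' @param seed integer seed.
#' @param epochHook optional `function(epoch)` returning the feature
#'   matrix to use that epoch (for per-epoch augmentation); when supplied,
#'   `X` provides only the shape.
#' @return An object of class `necaxrNet`.
#' @seealso [netPredict()]
#' @export
netFit <- function(X, y, hidden = 32L, lr = 0.001, batchSize = 16L,
                   epochs = 30L, seed = 0L, epochHook = NULL) {
    stopifnot(is.matrix(X), is.factor(y), nrow(X) == length(y),
              lr > 0, batchSize >= 1L, epochs >= 1L)
    d <- ncol(X); k <- nlevels(y); n <- nrow(X)
    Y <- diag(k)[as.integer(y), , drop = FALSE]
    w <- withSeed(seed, {
        if (hidden > 0L) {
            list(W1 = matrix(rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden),
                 b1 = rep(0, hidden),
                 W2 = matrix(rnorm(hidden * k, 0, sqrt(2 / hidden)),
                             hidden, k),
                 b2 = rep(0, k))
        } else {
            list(W2 = matrix(0, d, k), b2 = rep(0, k))
        }
    })
    state <- list(w = w, m = lapply(w, function(x) x * 0),
                  v = lapply(w, function(x) x * 0), t = 0L)
    orderSeeds <- deriveSeeds(seed + 1L, epochs)
    for (ep in seq_len(epochs)) {
        Xe <- if (is.null(epochHook)) X else epochHook(ep)
        ord <- withSeed(orderSeeds[ep], sample.int(n))
        for (start in seq(1L, n, by = batchSize)) {
            idx <- ord[start:min(start + batchSize - 1L, n)]
            xb <- Xe[idx, , drop = FALSE]
            yb <- Y[idx, , drop = FALSE]
            m <- nrow(xb)
            w <- state$w
            if (hidden > 0L) {
                a1 <- xb %*% w$W1
                a1 <- sweep(a1, 2, w$b1, `+`)
                h1 <- pmax(a1, 0)
                z <- sweep(h1 %*% w$W2, 2, w$b2, `+`)
                p <- .softmax(z)
                dz <- (p - yb) / m
                dh <- dz %*% t(w$W2)
                dh[a1 <= 0] <- 0
                grads <- list(W1 = t(xb) %*% dh, b1 = colSums(dh),
                              W2 = t(h1) %*% dz, b2 = colSums(dz))
            } else {
                z <- sweep(xb %*% w$W2, 2, w$b2, `+`)
                p <- .softmax(z)
                dz <- (p - yb) / m
                grads <- list(W2 = t(xb) %*% dz, b2 = colSums(dz))
            }
            if (any(!is.finite(unlist(grads))))
                stop("non-finite loss gradient during training")
            state <- .adamStep(state, grads, lr)
        }
    }
    structure(list(w = state$w, hidden = hidden, levels = levels(y)),
              class = "necaxrNet")
}

#' Predict class probabilities from a fitted network
#'
#' @param model a `necaxrNet` from [netFit()].
#' @param X numeric feature matrix.
#' @param type `"prob"` for the probability matrix, `"class"` for the
#'   argmax label (the class with the highest probability is selected).
#' @return A probability matrix or a factor of predicted labels.
#' @export
netPredict <- function(model, X, type = c("prob", "class")) {
    type <- match.arg(type)
    w <- model$w
    if (model$hidden > 0L) {
        h1 <- pmax(sweep(X %*% w$W1, 2, w$b1, `+`), 0)
        z <- sweep(h1 %*% w$W2, 2, w$b2, `+`)
    } else {
        z <- sweep(X %*% w$W2, 2, w$b2, `+`)
    }
    p <- .softmax(z)
    colnames(p) <- model$levels
    if (type == "prob") return(p)
    factor(model$levels[max.col(p, ties.method = "first")],
           levels = model$levels)
}
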