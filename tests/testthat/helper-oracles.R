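# Independent brute-force oracles, written from the operator definitions
# with explicit loops and index arithmetic; they share no code with the
# package implementations.

# mirror an out-of-range index under symmetric (edge-repeating) extension
mirrorIdx <- function(i, n) {
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n + 1 - i)
  i
}

# nested-loop sliding-window correlation with symmetric boundaries
oracleConv2d <- function(m, kernel) {
  h <- nrow(m); w <- ncol(m)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
          rr <- mirrorIdx(r + i - 1 - ry, h)
          cc <- mirrorIdx(c + j - 1 - rx, w)
          acc <- acc + kernel[i, j] * m[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# direct (non-separable) truncated-Gaussian blur
oracleGaussBlur <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  x <- seq(-r, r)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  oracleConv2d(m, k2)
}

oracleUnsharp <- function(m, sigma, amount) {
  m + amount * (m - oracleGaussBlur(m, sigma))
}

# global histogram equalisation from the CDF definition
oracleHistEq <- function(m, nbins = 256L) {
  v <- as.vector(m)
  b <- pmin(floor(v * nbins) + 1L, nbins)
  counts <- sapply(seq_len(nbins), function(k) sum(b == k))
  cdf <- cumsum(counts) / length(v)
  cdfmin <- cdf[which(counts > 0)[1]]
  if (1 - cdfmin <= 0) return(m)
  matrix(pmin(pmax((cdf[b] - cdfmin) / (1 - cdfmin), 0), 1), nrow(m))
}

# CLAHE oracle: per-tile clipped mapping computed independently, then
# per-pixel bilinear interpolation over the four surrounding tile centres.
oracleClahe <- function(m, tilesY, tilesX, clipLimit = Inf, nbins = 256L) {
  h <- nrow(m); w <- ncol(m)
  rowBreaks <- floor(seq(0, h, length.out = tilesY + 1))
  colBreaks <- floor(seq(0, w, length.out = tilesX + 1))
  cy <- (rowBreaks[-1] + rowBreaks[-(tilesY + 1)] + 1) / 2
  cx <- (colBreaks[-1] + colBreaks[-(tilesX + 1)] + 1) / 2
  # tile mapping evaluated at an intensity value (or identity if degenerate)
  tileMap <- vector("list", tilesY * tilesX)
  for (i in seq_len(tilesY)) {
    for (j in seq_len(tilesX)) {
      tv <- as.vector(m[(rowBreaks[i] + 1):rowBreaks[i + 1],
                        (colBreaks[j] + 1):colBreaks[j + 1]])
      b <- pmin(floor(tv * nbins) + 1L, nbins)
      counts <- sapply(seq_len(nbins), function(k) sum(b == k))
      deg <- sum(counts > 0) <= 1
      lut <- NULL
      if (!deg) {
        hh <- counts
        if (is.finite(clipLimit)) {
          lim <- clipLimit * length(tv) / nbins
          excess <- sum(pmax(hh - lim, 0))
          hh <- pmin(hh, lim) + excess / nbins
        }
        cdf <- cumsum(hh) / sum(hh)
        cdfmin <- cdf[which(hh > 0)[1]]
        if (1 - cdfmin <= 0) deg <- TRUE
        else lut <- pmin(pmax((cdf - cdfmin) / (1 - cdfmin), 0), 1)
      }
      tileMap[[(j - 1) * tilesY + i]] <-
        if (deg) function(v) v else local({ l <- lut; function(v)
          l[pmin(floor(v * nbins) + 1L, nbins)] })
    }
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    ti <- max(which(cy <= r), 1L)
    if (length(which(cy <= r)) == 0) ti <- 1L
    tiN <- min(ti + 1L, tilesY)
    wy <- if (tiN > ti) (r - cy[ti]) / (cy[tiN] - cy[ti]) else 0
    wy <- min(max(wy, 0), 1)
    for (c in seq_len(w)) {
      tj <- max(which(cx <= c), 1L)
      if (length(which(cx <= c)) == 0) tj <- 1L
      tjN <- min(tj + 1L, tilesX)
      wx <- if (tjN > tj) (c - cx[tj]) / (cx[tjN] - cx[tj]) else 0
      wx <- min(max(wx, 0), 1)
      v <- m[r, c]
      f <- function(i, j) tileMap[[(j - 1) * tilesY + i]](v)
      out[r, c] <- (1 - wy) * (1 - wx) * f(ti, tj) +
                   (1 - wy) * wx * f(ti, tjN) +
                   wy * (1 - wx) * f(tiN, tj) +
                   wy * wx * f(tiN, tjN)
    }
  }
  pmin(pmax(out, 0), 1)
}

# dense direct solve of the illumination refinement system, with forward
# difference matrices built entry by entry
oracleLimeRefine <- function(tHat, alpha, epsilon,
                             strategy = "inverse_gradient") {
  h <- nrow(tHat); w <- ncol(tHat); n <- h * w
  idx <- function(i, j) i + (j - 1) * h
  Dh <- matrix(0, n, n); Dv <- matrix(0, n, n)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      p <- idx(i, j)
      if (j < w) { Dh[p, p] <- -1; Dh[p, idx(i, j + 1)] <- 1 }
      if (i < h) { Dv[p, p] <- -1; Dv[p, idx(i + 1, j)] <- 1 }
    }
  }
  b <- as.vector(tHat)
  if (strategy == "inverse_gradient") {
    wh <- 1 / (abs(Dh %*% b) + epsilon)
    wv <- 1 / (abs(Dv %*% b) + epsilon)
  } else {
    wh <- rep(1, n); wv <- rep(1, n)
  }
  A <- diag(n) + alpha * (t(Dh) %*% diag(as.vector(wh)) %*% Dh +
                          t(Dv) %*% diag(as.vector(wv)) %*% Dv)
  solve(A, b)
}

# sort-based type-7 percentile (linear interpolation of order statistics)
oraclePercentile <- function(v, p) {
  s <- sort(v)
  hidx <- (length(s) - 1) * p + 1
  lo <- floor(hidx)
  if (lo >= length(s)) return(s[length(s)])
  s[lo] + (hidx - lo) * (s[lo + 1] - s[lo])
}

# confusion-matrix metrics computed from first principles
oracleMetrics <- function(yTrue, yPred, classes) {
  k <- length(classes)
  cm <- matrix(0, k, k, dimnames = list(true = classes, pred = classes))
  for (i in seq_along(yTrue))
    cm[yTrue[i], yPred[i]] <- cm[yTrue[i], yPred[i]] + 1
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  c(accuracy = sum(diag(cm)) / sum(cm), precision = mean(prec),
    recall = mean(rec), f1 = mean(f1))
}

randImage <- function(seed, h = 16L, w = 16L, lo = 0, hi = 1) {
  set.seed(seed)
  GrayImage(matrix(runif(h * w, lo, hi), h, w))
}

histEntropy <- function(m, nbins = 64L) {
  b <- pmin(floor(as.vector(m) * nbins) + 1L, nbins)
  p <- tabulate(b, nbins) / length(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}
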