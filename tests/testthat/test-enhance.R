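test_that("sharpening preserves flat regions and matches hand convolution", {
  cst <- GrayImage(matrix(0.5, 16, 16))
  expect_identical(pixels(sharpen(cst)), pixels(cst))

  # lone bright pixel: centre 5*0.1, 4-neighbours -0.1 clipped to 0
  m <- matrix(0, 9, 9); m[5, 5] <- 0.1
  out <- pixels(sharpen(GrayImage(m)))
  expect_equal(out[5, 5], 0.5)
  expect_equal(out[4, 5], 0)   # clipped from -0.1
  raw <- sharpen(GrayImage(m), clip = FALSE)
  expect_equal(raw[4, 5], -0.1)
  expect_equal(raw[5, 4], -0.1)
  expect_equal(sum(raw != 0), 5)

  expect_error(sharpen(cst, kernel = matrix(1, 3, 3)), "sum to 1")
})

test_that("sharpen agrees with the nested-loop convolution oracle", {
  k <- sharpenKernel()
  for (s in 1:10) {
    img <- randImage(s)
    expect_lt(max(abs(sharpen(img, k, clip = FALSE) -
                      oracleConv2d(pixels(img), k))), 1e-12)
  }
  # a non-symmetric intensity-preserving kernel exercises the boundary code
  k2 <- matrix(c(0.1, 0.2, 0, 0.3, 0.4, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  img <- randImage(99)
  expect_lt(max(abs(sharpen(img, k2, clip = FALSE) -
                    oracleConv2d(pixels(img), k2))), 1e-12)
})

test_that("histogram equalisation follows the cdf mapping", {
  # half 0 / half 1
  m <- matrix(rep(c(0, 1), 32), 8, 8)
  out <- pixels(histEqualize(GrayImage(m)))
  expect_identical(out[m == 0], rep(0, 32))
  expect_identical(out[m == 1], rep(1, 32))

  # four equally occupied levels keep their rank spacing
  m4 <- matrix(rep(c(0, 1 / 3, 2 / 3, 1), 16), 8, 8)
  out4 <- pixels(histEqualize(GrayImage(m4)))
  expect_equal(sort(unique(as.vector(out4))), c(0, 1 / 3, 2 / 3, 1),
               tolerance = 1e-12)

  # constant image: degenerate cdf, returned unchanged
  cst <- GrayImage(matrix(0.42, 8, 8))
  expect_identical(pixels(histEqualize(cst)), pixels(cst))

  # random images match the independent cdf oracle
  for (s in 1:5) {
    img <- randImage(s)
    expect_equal(pixels(histEqualize(img)), oracleHistEq(pixels(img)),
                 tolerance = 1e-12)
  }
})

test_that("equalisation is monotone and idempotent up to binning", {
  nbins <- 256L
  for (s in 1:6) {
    img <- randImage(s, 20, 20)
    out <- pixels(histEqualize(img, nbins))
    v <- as.vector(pixels(img)); o <- as.vector(out)
    ord <- order(v)
    expect_true(all(diff(o[ord]) >= -1e-12))
    twice <- pixels(histEqualize(histEqualize(img, nbins), nbins))
    expect_lte(max(abs(twice - out)), 2 / nbins)
  }
})

test_that("CLAHE reduces to global equalisation with one unclipped tile", {
  for (s in 1:4) {
    img <- randImage(s, 24, 24)
    single <- clahe(img, claheParams(1, 1, Inf, 256))
    expect_lte(max(abs(pixels(single) - pixels(histEqualize(img, 256)))),
               1 / 256)
  }
})

test_that("CLAHE leaves constant images unchanged", {
  cst <- GrayImage(matrix(0.37, 32, 32))
  expect_equal(pixels(clahe(cst)), pixels(cst), tolerance = 1e-12)
  expect_equal(pixels(clahe(cst, claheParams(4, 4, 1.5))), pixels(cst),
               tolerance = 1e-12)
})

test_that("CLAHE matches the per-tile interpolation oracle", {
  for (s in 1:10) {
    img <- randImage(s)
    got <- pixels(clahe(img, claheParams(2, 2, 2.0, 64)))
    want <- oracleClahe(pixels(img), 2, 2, 2.0, 64)
    expect_lt(max(abs(got - want)), 1e-10)
  }
  # unclipped variant and a non-square grid on a non-square image
  img <- randImage(41, 18, 30)
  expect_lt(max(abs(pixels(clahe(img, claheParams(3, 2, Inf, 128))) -
                    oracleClahe(pixels(img), 3, 2, Inf, 128))), 1e-10)
  expect_error(clahe(randImage(1, 8, 8), claheParams(9, 2)), "larger")
})

test_that("unsharp masking is exact at amount 0 and on constants", {
  img <- randImage(3)
  expect_identical(pixels(unsharpMask(img, 1.2, 0)), pixels(img))
  cst <- GrayImage(matrix(0.61, 12, 12))
  expect_equal(pixels(unsharpMask(cst, 2, 1.5)), pixels(cst),
               tolerance = 1e-12)
})

test_that("unsharp masking matches the direct Gaussian oracle", {
  # step edge: overshoot/undershoot flanks the transition
  m <- matrix(0.2, 16, 16); m[, 9:16] <- 0.8
  img <- GrayImage(m)
  want <- oracleUnsharp(m, 1, 1)
  got <- unsharpMask(img, 1, 1, clip = FALSE)
  expect_lt(max(abs(got - want)), 1e-10)
  expect_gt(max(want), 0.8)   # overshoot
  expect_lt(min(want), 0.2)   # undershoot
  for (s in 1:10) {
    img <- randImage(s)
    expect_lt(max(abs(unsharpMask(img, 1.5, 0.7, clip = FALSE) -
                      oracleUnsharp(pixels(img), 1.5, 0.7))), 1e-10)
  }
})

test_that("percentile compression stretches between its percentiles", {
  # full-range percentiles = min-max stretch
  m <- matrix(seq(0.2, 0.8, length.out = 64), 8, 8)
  out <- pixels(compressHistogram(GrayImage(m), 0, 100))
  expect_equal(range(out), c(0, 1), tolerance = 1e-12)
  expect_equal(out, (m - 0.2) / 0.6, tolerance = 1e-12)

  cst <- GrayImage(matrix(0.5, 8, 8))
  expect_identical(pixels(compressHistogram(cst)), pixels(cst))

  # 100-pixel ramp against the sort-based percentile oracle
  v <- matrix(seq(0, 0.99, by = 0.01), 10, 10)
  img <- GrayImage(v)
  lo <- oraclePercentile(as.vector(v), 0.10)
  hi <- oraclePercentile(as.vector(v), 0.90)
  want <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  expect_equal(pixels(compressHistogram(img, 10, 90)), want,
               tolerance = 1e-12)
  expect_true(all(pixels(compressHistogram(img, 10, 90))[v <= lo] == 0))
  expect_true(all(pixels(compressHistogram(img, 10, 90))[v >= hi] == 1))
})

test_that("inversion is an exact involution", {
  img <- randImage(8)
  expect_identical(pixels(invertImage(invertImage(img))), pixels(img))
  expect_true(all(pixels(invertImage(GrayImage(matrix(0, 8, 8)))) == 1))
  m <- matrix(0.3, 8, 8)
  expect_equal(pixels(invertImage(GrayImage(m))), matrix(0.7, 8, 8),
               tolerance = 1e-15)
})

test_that("all enhancement operators keep intensities in [0, 1] and are deterministic", {
  ops <- list(
    function(x) sharpen(x),
    function(x) histEqualize(x),
    function(x) clahe(x, claheParams(4, 4)),
    function(x) unsharpMask(x, 1, 2),
    function(x) compressHistogram(x),
    function(x) limeEnhance(x),
    function(x) invertImage(x))
  for (s in 1:10) {
    img <- randImage(s, 16, 16)
    for (op in ops) {
      out <- op(img)
      expect_true(all(pixels(out) >= 0 & pixels(out) <= 1))
      expect_identical(pixels(op(img)), pixels(out))
    }
  }
})
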