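test_that("translation shifts by whole pixels with zero fill", {
  m <- matrix(0, 8, 8); diag(m) <- 1
  img <- GrayImage(m)
  down <- pixels(translateImage(img, 1, 0))
  expect_true(all(down[1, ] == 0))
  expect_identical(down[2:8, ], m[1:7, ])
  right <- pixels(translateImage(img, 0, 2))
  expect_true(all(right[, 1:2] == 0))
  expect_identical(right[, 3:8], m[, 1:6])
  # off-frame shift empties the image
  expect_true(all(pixels(translateImage(img, 10, 0)) == 0))
})

test_that("random translation respects its maximum shift", {
  img <- randImage(1, 100, 100)
  set.seed(42)
  # maxFrac 0 is the exact identity
  expect_identical(pixels(randomTranslate(img, 0)), pixels(img))
  # shifts at 10% of length never exceed 10 pixels: detect the applied
  # shift by locating a planted bright pixel
  m <- matrix(0, 100, 100); m[50, 50] <- 1
  pin <- GrayImage(m)
  set.seed(7)
  for (i in 1:200) {
    out <- pixels(randomTranslate(pin, 0.10))
    hit <- which(out == 1, arr.ind = TRUE)
    expect_equal(nrow(hit), 1L)
    expect_lte(max(abs(hit - c(50, 50))), 10)
  }
})

test_that("flips are exact involutions and compose to a 180-degree turn", {
  img <- randImage(5)
  for (ax in c("horizontal", "vertical"))
    expect_identical(pixels(flipImage(flipImage(img, ax), ax)), pixels(img))
  m <- pixels(img)
  expect_identical(pixels(flipImage(img, "horizontal"))[1, ], rev(m[1, ]))
  hv <- flipImage(flipImage(img, "horizontal"), "vertical")
  expect_identical(pixels(hv), pixels(rotateImage(img, 180)))
  # 2x2 block check on an 8x8: [[a,b],[c,d]] -> [[b,a],[d,c]] horizontally
  expect_identical(pixels(flipImage(img, "horizontal")),
                   m[, ncol(m):1])
})

test_that("rotation identities hold on the grid", {
  img <- randImage(6, 15, 15)
  expect_identical(pixels(rotateImage(img, 0)), pixels(img))
  expect_lt(max(abs(pixels(rotateImage(img, 360)) - pixels(img))), 1e-6)
  set.seed(13)
  expect_equal(dim(randomRotate(img, 20)), dim(img))
})

test_that("rotation by quarter turns equals transpose plus flip", {
  img <- randImage(9, 12, 12)
  m <- pixels(img)
  tm <- t(m)
  # -90 (clockwise in matrix terms): transpose then vertical flip
  expect_identical(pixels(rotateImage(img, -90, method = "nearest")),
                   tm[nrow(tm):1, ])
  # +90: transpose then horizontal flip
  expect_identical(pixels(rotateImage(img, 90, method = "nearest")),
                   tm[, ncol(tm):1])
})

test_that("crop-resize is the identity on the full frame and on constants", {
  img <- randImage(2, 20, 20)
  expect_equal(pixels(cropResize(img, 1, 1, 20)), pixels(img),
               tolerance = 1e-15)
  cst <- GrayImage(matrix(0.44, 20, 20))
  expect_equal(pixels(cropResize(cst, 3, 5, 10)), pixels(cst),
               tolerance = 1e-12)
  set.seed(3)
  expect_equal(dim(randomCropResize(img, 11)), c(20L, 20L))
  expect_error(randomCropResize(img, 25), "exceeds")
})

test_that("random crop windows cover exactly the valid positions", {
  img <- randImage(4, 64, 64)
  # plant a gradient so the window position is recoverable from corner value
  m <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  img <- GrayImage(m)
  set.seed(11)
  tops <- integer(500)
  for (i in 1:500) {
    out <- pixels(randomCropResize(img, 33))
    # corner of resized window equals the window's corner (corner-aligned)
    src <- which(abs(m - out[1, 1]) < 1e-12, arr.ind = TRUE)
    expect_equal(nrow(src), 1L)
    tops[i] <- src[1, 1]
    expect_lte(src[1, 1], 32); expect_lte(src[1, 2], 32)
  }
  expect_setequal(range(tops), c(1L, 32L))
})

test_that("occlusion zeroes one rectangle of the requested area", {
  ones <- GrayImage(matrix(1, 100, 100))
  set.seed(5)
  for (i in 1:50) {
    out <- pixels(randomOcclude(ones, 0.05))
    expect_equal(mean(out), 0.95, tolerance = 2e-3)
    expect_true(all(out %in% c(0, 1)))
  }
  for (i in 1:50) {
    out <- pixels(randomOcclude(ones, 0.25))
    expect_gte(mean(out == 0), 0.24)
    expect_lte(mean(out == 0), 0.26)
  }
  # the complement is untouched
  img <- randImage(12, 50, 50)
  set.seed(9)
  out <- pixels(randomOcclude(img, 0.10))
  changed <- out != pixels(img)
  expect_true(all(out[changed] == 0))
})

test_that("additive Gaussian noise has the requested moments", {
  cst <- GrayImage(matrix(0.5, 1000, 1000))
  set.seed(8)
  out <- pixels(randomNoise(cst, 0.05))
  expect_gte(mean(out), 0.499); expect_lte(mean(out), 0.501)
  expect_gte(sd(out), 0.049); expect_lte(sd(out), 0.051)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("policy application is ordered, gated and reproducible", {
  img <- randImage(3, 32, 32)
  empty <- AugmentPolicy(list(), seed = 1)
  expect_identical(pixels(applyPolicy(img, empty)), pixels(img))

  dbl <- AugmentPolicy(list(AugmentSpec("hflip", 1), AugmentSpec("hflip", 1)),
                       seed = 1)
  expect_identical(pixels(applyPolicy(img, dbl)), pixels(img))

  never <- AugmentPolicy(list(AugmentSpec("inversion", 0)), seed = 2)
  expect_identical(pixels(applyPolicy(img, never)), pixels(img))

  pol <- standardPolicy(c("translation", "rotation", "noise"), seed = 7)
  a <- applyPolicy(img, pol)
  b <- applyPolicy(img, pol)
  expect_identical(pixels(a), pixels(b))
  c2 <- applyPolicy(img, pol, seed = 8)
  expect_false(identical(pixels(a), pixels(c2)))
  expect_true(all(pixels(a) >= 0 & pixels(a) <= 1))
})

test_that("the audit log records every spec and its gate", {
  img <- randImage(4, 16, 16)
  pol <- AugmentPolicy(list(AugmentSpec("hflip", 1),
                            AugmentSpec("vflip", 0)), seed = 5)
  res <- applyPolicy(img, pol, audit = TRUE)
  expect_equal(res$audit$name, c("hflip", "vflip"))
  expect_equal(res$audit$applied, c(TRUE, FALSE))
  expect_identical(pixels(res$image), pixels(flipImage(img, "horizontal")))
})

test_that("a shared plan keeps multi-channel transforms aligned", {
  g1 <- randImage(1, 24, 24); g2 <- randImage(2, 24, 24)
  g3 <- randImage(3, 24, 24)
  mci <- MultiChannelImage(list(g1, g2, g3))
  pol <- standardPolicy("translation", seed = 4)
  out <- applyPolicyMulti(mci, pol, seed = 21)
  # the same shift applies to each channel: zero borders coincide
  z1 <- pixels(getChannel(out, 1)) == 0
  z2 <- pixels(getChannel(out, 2)) == 0
  expect_true(all(z1[pixels(getChannel(out, 1)) == 0] ==
                  z2[pixels(getChannel(out, 1)) == 0]))
  one <- applyPolicy(g1, pol, seed = 21)
  expect_identical(pixels(getChannel(out, 1)), pixels(one))
})

test_that("invalid augmentation specs are rejected", {
  expect_error(AugmentSpec("warp", 0.5), "unknown augmentation")
  expect_error(AugmentSpec("translation", 2), "chance")
  expect_error(AugmentSpec("translation", 0.5, 0.9), "out of range")
  expect_error(AugmentSpec("occlusion", 0.5, 1.5), "out of range")
})
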