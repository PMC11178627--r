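test_that("GrayImage enforces its invariants", {
  expect_s4_class(GrayImage(matrix(0.5, 8, 8)), "GrayImage")
  expect_error(GrayImage(matrix(0.5, 4, 8)), "8x8")
  expect_error(GrayImage(matrix(1.5, 8, 8)), "0, 1")
  expect_error(GrayImage(matrix(c(NA_real_, rep(0.1, 63)), 8, 8)), "finite")
})

test_that("MultiChannelImage requires three aligned channels", {
  g <- GrayImage(matrix(0.3, 8, 8))
  expect_s4_class(MultiChannelImage(list(g, g, g)), "MultiChannelImage")
  expect_error(MultiChannelImage(list(g, g)), "exactly 3")
  g2 <- GrayImage(matrix(0.3, 8, 10))
  expect_error(MultiChannelImage(list(g, g, g2)), "share")
})

test_that("PNG intensities rescale by the container bit depth", {
  vals <- matrix(rep(c(0, 128 / 255, 1), length.out = 64), 8, 8)
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(vals, p)
  img <- readGrayImage(p)
  expect_equal(sort(unique(as.vector(pixels(img)))), c(0, 128 / 255, 1))

  pAll <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 8, 8), pAll)
  expect_true(all(pixels(readGrayImage(pAll)) == 1))
})

test_that("16-bit TIFF extremes map to 0 and 1", {
  vals <- matrix(rep(c(0, 1), 32), 8, 8)
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(vals, p, bits.per.sample = 16L)
  expect_equal(sort(unique(as.vector(pixels(readGrayImage(p))))), c(0, 1))
})

test_that("multi-channel sources are averaged on read", {
  a <- array(0, c(8, 8, 3))
  a[, , 1] <- 0.2; a[, , 2] <- 0.4; a[, , 3] <- 0.6
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(a, p)
  expect_equal(pixels(readGrayImage(p)), matrix(0.4, 8, 8),
               tolerance = 1 / 255)
})

test_that("write/read round trip stays within the quantisation bound", {
  for (s in 1:5) {
    img <- randImage(s, 12, 9)
    for (case in list(c("png", 8), c("tif", 8), c("tif", 16))) {
      p <- withr::local_tempfile(fileext = paste0(".", case[1]))
      writeImage(img, p, bitDepth = as.integer(case[2]))
      back <- readGrayImage(p)
      expect_lt(max(abs(pixels(back) - pixels(img))),
                1 / (2^as.integer(case[2]) - 1) + 1e-12)
    }
  }
  # all-zeros and all-0.5 exact cases
  z <- GrayImage(matrix(0, 8, 8))
  p <- withr::local_tempfile(fileext = ".png")
  writeImage(z, p)
  expect_true(all(pixels(readGrayImage(p)) == 0))
  hf <- GrayImage(matrix(0.5, 8, 8))
  writeImage(hf, p)
  expect_lte(max(abs(pixels(readGrayImage(p)) - 0.5)), 1 / 255)
})

test_that("a MultiChannelImage writes as three aligned planes", {
  g1 <- randImage(1, 8, 8); g2 <- randImage(2, 8, 8); g3 <- randImage(3, 8, 8)
  mci <- MultiChannelImage(list(g1, g2, g3))
  p <- withr::local_tempfile(fileext = ".png")
  writeImage(mci, p)
  arr <- png::readPNG(p)
  expect_equal(dim(arr), c(8L, 8L, 3L))
  expect_lt(max(abs(arr[, , 2] - pixels(g2))), 1 / 255 + 1e-12)
})

test_that("PNG refuses 16-bit and unknown formats are rejected", {
  img <- randImage(4, 8, 8)
  expect_error(writeImage(img, withr::local_tempfile(fileext = ".png"),
                          bitDepth = 16L), "TIFF")
  expect_error(readGrayImage("no/such/file.png"), "not found")
  bad <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", bad)
  expect_error(readGrayImage(bad), "unsupported")
})

test_that("toThreeChannel replicates the input exactly", {
  img <- randImage(7, 10, 12)
  mci <- toThreeChannel(img)
  expect_equal(dim(mci), c(10L, 12L))
  for (i in 1:3)
    expect_identical(pixels(getChannel(mci, i)), pixels(img))
  expect_true(validObject(mci))
  cst <- toThreeChannel(GrayImage(matrix(0.7, 8, 8)))
  expect_true(all(vapply(channels(cst),
                         function(g) all(pixels(g) == 0.7), logical(1))))
})

test_that("DICOM frames decode, normalise and respect photometric", {
  set.seed(20)
  vals <- matrix(sample.int(3900L, 96, replace = TRUE) + 150L, 8, 12)
  vals[1, 1] <- 100L; vals[8, 12] <- 4095L   # pin stored min/max
  p <- withr::local_tempfile(fileext = ".dcm")
  writeTestDicom(p, vals)
  img <- readGrayImage(p)
  expect_equal(dim(img), c(8L, 12L))
  expect_equal(pixels(img), (vals - 100) / (4095 - 100), tolerance = 1e-12)

  # MONOCHROME1 is inverted so that brighter = higher
  writeTestDicom(p, vals, photometric = "MONOCHROME1")
  expect_equal(pixels(readGrayImage(p)),
               1 - (vals - 100) / (4095 - 100), tolerance = 1e-12)

  # rescale slope/intercept are applied before windowing
  writeTestDicom(p, vals, slope = 2, intercept = -100)
  expect_equal(pixels(readGrayImage(p)), (vals - 100) / (4095 - 100),
               tolerance = 1e-12)
})

test_that("a zero-dynamic-range DICOM reads as zeros with a warning", {
  vals <- matrix(777L, 8, 8)
  p <- withr::local_tempfile(fileext = ".dcm")
  writeTestDicom(p, vals)
  expect_warning(img <- readGrayImage(p), "zero dynamic range")
  expect_true(all(pixels(img) == 0))
})
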