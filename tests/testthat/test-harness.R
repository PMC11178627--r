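test_that("fold assignment is stratified, exhaustive and deterministic", {
  labs <- rep(c("NP", "mNEC", "sNEC"), each = 5)
  fs <- makeFolds(labs, k = 5, seed = 1)
  tab <- table(labs, foldAssignments(fs))
  expect_true(all(tab == 1L))
  expect_identical(foldAssignments(makeFolds(labs, k = 5, seed = 1)),
                   foldAssignments(fs))
  expect_false(identical(foldAssignments(makeFolds(labs, k = 5, seed = 2)),
                         foldAssignments(fs)))
  expect_error(makeFolds(rep(c("NP", "mNEC"), c(10, 3)), k = 5), "at least k")

  # unbalanced label counts still differ by at most one per fold
  for (s in 1:5) {
    set.seed(s)
    labs2 <- sample(c("NP", "mNEC", "sNEC"), 40 + s, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    k <- sample(3:6, 1)
    if (min(table(labs2)) < k) next
    fs2 <- makeFolds(labs2, k = k, seed = s)
    expect_true(validObject(fs2))
    for (lab in unique(labs2)) {
      cnt <- tabulate(foldAssignments(fs2)[labs2 == lab], k)
      expect_lte(max(cnt) - min(cnt), 1L)
    }
  }
})

test_that("metrics follow the macro-averaged confusion-matrix definitions", {
  expect_equal(unname(computeMetrics(c("a", "b", "c"), c("a", "b", "c"))),
               rep(1, 4))

  # constant single-class prediction on a balanced 3-class set
  yt <- rep(c("NP", "mNEC", "sNEC"), each = 10)
  yp <- rep("NP", 30)
  m <- computeMetrics(yt, yp, classes = c("NP", "mNEC", "sNEC"))
  expect_equal(unname(m["accuracy"]), 1 / 3)
  expect_equal(unname(m["recall"]), 1 / 3)
  expect_equal(unname(m["precision"]), 1 / 9)

  expect_error(computeMetrics(c("a", "b"), c("a")), "equal")

  # random cases against the independent confusion-matrix oracle
  classes <- c("NP", "mNEC", "sNEC")
  for (s in 1:20) {
    set.seed(s)
    yt <- sample(classes, 30, replace = TRUE)
    yp <- sample(classes, 30, replace = TRUE)
    expect_equal(computeMetrics(yt, yp, classes = classes),
                 oracleMetrics(yt, yp, classes), tolerance = 1e-12)
  }
})

test_that("the softmax network separates simple Gaussian classes", {
  set.seed(1)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2, -2), n, 2), matrix(rnorm(n * 2, 0), n, 2),
             matrix(rnorm(n * 2, 2), n, 2))
  y <- factor(rep(c("a", "b", "c"), each = n))
  m <- netFit(X, y, hidden = 8, epochs = 60, lr = 0.01, seed = 1)
  expect_gt(mean(netPredict(m, X, type = "class") == y), 0.85)
  p <- netPredict(m, X)
  expect_equal(rowSums(p), rep(1, nrow(X)), tolerance = 1e-9)
  # seeded refits are bit-identical
  m2 <- netFit(X, y, hidden = 8, epochs = 60, lr = 0.01, seed = 1)
  expect_identical(m$w, m2$w)
  expect_error(netFit(X, y, epochs = 0), "epochs")
})

test_that("cross-validated training learns separable phantoms above chance", {
  labs <- rep(c("NP", "mNEC", "sNEC"), each = 10)
  imgs <- lapply(seq_along(labs), function(i)
    generatePhantom(PhantomSpec(labs[i], lesionContrast = 0.9,
                                noiseSigma = 0.01, seed = 500 + i))$image)
  fs <- makeFolds(labs, k = 5, seed = 2)
  cfg <- trainConfig(pipeline = "baseline", epochs = 25, seed = 3)
  rep1 <- trainEval(imgs, labs, fs, cfg)
  expect_s4_class(rep1, "MetricsReport")
  expect_equal(nrow(perFold(rep1)), 5L)
  expect_gt(mean(perFold(rep1)$accuracy), 1 / 3)
  expect_true(all(unlist(perFold(rep1)[-1]) >= 0 &
                  unlist(perFold(rep1)[-1]) <= 1))

  # identical config and seed reproduce the report exactly
  rep2 <- trainEval(imgs, labs, fs, cfg)
  expect_identical(perFold(rep1), perFold(rep2))
  expect_equal(fingerprint(rep1)$pipeline, "baseline")
})

test_that("trainEval accepts a manifest and applies a policy", {
  d <- withr::local_tempdir()
  man <- generateDataset(5, baseSeed = 300, outDir = d,
                         height = 64, width = 64, lesionContrast = 0.9,
                         noiseSigma = 0.01)
  fs <- makeFolds(man, k = 5, seed = 1)
  cfg <- trainConfig(pipeline = "pr1", policy = standardPolicy("translation"),
                     epochs = 4, trainSize = 16L, seed = 1)
  rep1 <- trainEval(man, folds = fs, config = cfg)
  expect_equal(nrow(perFold(rep1)), 5L)
  expect_equal(fingerprint(rep1)$policy, "translation")
})

test_that("run comparison reports deltas and Welch p-values", {
  mkReport <- function(acc) {
    new("MetricsReport",
        perFold = data.frame(fold = seq_along(acc), accuracy = acc,
                             precision = acc, recall = acc, f1 = acc),
        fingerprint = list())
  }
  a <- mkReport(rep(0.9, 5)); b <- mkReport(rep(0.5, 5))
  self <- compareRuns(list(base = a, same = a), baseline = "base")
  expect_equal(self$deltaAccuracy, 0)
  expect_equal(self$pValue, 1)

  cmp <- compareRuns(list(base = b, high = a), baseline = "base")
  expect_equal(cmp$deltaAccuracy, 0.4)
  expect_lt(cmp$pValue, 0.001)

  three <- compareRuns(list(base = b, r1 = a, r2 = b), baseline = 1L)
  expect_equal(nrow(three), 2L)

  d <- mkReport(rep(0.5, 4))
  expect_error(compareRuns(list(a, d)), "same fold split")
})
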