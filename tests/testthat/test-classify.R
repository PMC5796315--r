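test_that("square truncation keeps the largest leading perfect square", {
  expect_equal(truncateSquare(numeric(3000))$side, 54)
  expect_length(truncateSquare(numeric(3000))$retained, 2916)
  expect_equal(truncateSquare(numeric(2916))$side, 54)
  expect_equal(truncateSquare(numeric(3050))$side, 55)
  expect_length(truncateSquare(numeric(3050))$retained, 3025)
  expect_error(truncateSquare(numeric(3)), "at least 4")
  # brute-force oracle over a sweep of lengths
  for (n in c(4, 10, 99, 100, 101, 530)) {
    sides <- 1:n
    best <- max(sides[sides^2 <= n])
    expect_equal(truncateSquare(numeric(n))$side, best)
  }
})

test_that("z-layout encoding fills row-major with affine greyscale mapping", {
  ramp <- 0:2915
  img <- encodeZLayout(ramp)
  m <- imageMatrix(img)
  expect_equal(dim(m), c(54, 54))
  expect_equal(m[1, 1], 0)
  expect_equal(m[54, 54], 255)
  expect_true(all(diff(as.vector(t(m))) >= 0))   # nondecreasing row-major

  # constant segment maps to uniform mid-grey
  expect_true(all(imageMatrix(encodeZLayout(rep(1.5, 64))) == 128))

  # invariance under positive affine amplitude transforms
  set.seed(2)
  seg <- rnorm(49)
  expect_equal(imageMatrix(encodeZLayout(2.5 * seg + 3)),
               imageMatrix(encodeZLayout(seg)), tolerance = 1e-12)

  expect_error(encodeZLayout(numeric(50)), "perfect square")
})

test_that("K-means separates well-separated blobs and honors its contracts", {
  set.seed(9)
  blobs <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
                 matrix(rnorm(60, 6, 0.2), ncol = 2),
                 matrix(rnorm(60, c(0, 12), 0.2), ncol = 2, byrow = TRUE))
  labs <- factor(rep(c("a", "b", "c"), each = 30))
  fit <- kmeansFit(blobs, 3, seed = 4)
  mapping <- mapClustersToLabels(fit$cluster, labs)
  expect_equal(mean(mapping[fit$cluster] == labs), 1.0)

  # k = #points: every point its own cluster, zero WCSS
  small <- blobs[1:5, ]
  fitAll <- kmeansFit(small, 5, seed = 1)
  expect_equal(fitAll$wcss, 0, tolerance = 1e-12)
  expect_equal(sort(fitAll$cluster), 1:5)

  # duplicating every point leaves the centroids unchanged
  fitDup <- kmeansFit(rbind(blobs, blobs), 3, seed = 4)
  ord <- function(cen) cen[order(cen[, 1], cen[, 2]), ]
  expect_equal(ord(fitDup$centroids), ord(fit$centroids), tolerance = 1e-8)

  # deterministic under a fixed seed
  expect_identical(kmeansFit(blobs, 3, seed = 11)$cluster,
                   kmeansFit(blobs, 3, seed = 11)$cluster)
  expect_error(kmeansFit(blobs, 999), "1 <= k")
})

test_that("the Lloyd fixed point matches an independent K-means on easy data", {
  set.seed(21)
  blobs <- rbind(matrix(rnorm(80, 0, 0.3), ncol = 2),
                 matrix(rnorm(80, 8, 0.3), ncol = 2))
  ours <- kmeansFit(blobs, 2, seed = 5)
  ref <- stats::kmeans(blobs, 2, nstart = 10)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("cluster-to-label mapping takes the training majority with stable ties", {
  labs <- factor(c(rep("AVB", 9), "SA", rep("SA", 5)),
                 levels = c("AVB", "SA"))
  cl <- c(rep(1, 10), rep(2, 5))
  expect_equal(mapClustersToLabels(cl, labs), c("AVB", "SA"))
  # adversarial 50/50 cluster: deterministic tie-break to the first level
  labs2 <- factor(c("AVB", "SA"), levels = c("AVB", "SA"))
  expect_equal(mapClustersToLabels(c(1, 1), labs2), "AVB")
})

test_that("evaluation reproduces brute-force one-vs-rest counting", {
  classes <- c("AVB", "SA", "STE")
  set.seed(33)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    ev <- evaluateClassifier(pred, truth, classes)
    pc <- perClassMetrics(ev)
    accs <- numeric(length(classes))
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      tn <- sum(pred != cl & truth != cl)
      expect_equal(pc$tp[ci], tp)
      expect_equal(pc$fp[ci], fp)
      expect_equal(pc$fn[ci], fn)
      expect_equal(pc$tn[ci], tn)
      expect_equal(tp + fp + fn + tn, n)
      accs[ci] <- (tp + tn) / n
    }
    expect_equal(unname(macroMetrics(ev)["accuracy"]), mean(accs),
                 tolerance = 1e-12)
    # conservation: cells sum to n, row sums are per-class truth counts
    expect_equal(sum(confusionMatrix(ev)), n)
    expect_equal(unname(rowSums(confusionMatrix(ev))),
                 unname(as.vector(table(factor(truth, classes)))))
  }
})

test_that("perfect predictions score 1.0 and the F1 identity holds", {
  truth <- rep(c("AVB", "SA", "STE"), each = 5)
  ev <- evaluateClassifier(truth, truth)
  expect_equal(unname(macroMetrics(ev)), rep(1, 4))
  m <- macroMetrics(ev)
  expect_equal(m[["f1"]], f1Score(m[["precision"]], m[["recall"]]))
})

test_that("stratified cross-validation partitions the data and is reproducible", {
  ds <- makeSegmentDataset(nPerClass = 12, segmentLength = 3000, seed = 3)
  ev <- crossValidate(ds$segments, ds$labels, folds = 4, seed = 3,
                      nstart = 10)
  # every sample appears in exactly one test fold: cells sum to n
  expect_equal(sum(confusionMatrix(ev)), nrow(ds$segments))
  expect_equal(nrow(ev@folds), 4)
  ev2 <- crossValidate(ds$segments, ds$labels, folds = 4, seed = 3,
                       nstart = 10)
  expect_identical(macroMetrics(ev), macroMetrics(ev2))
  expect_identical(confusionMatrix(ev), confusionMatrix(ev2))
  expect_error(crossValidate(ds$segments, ds$labels, folds = 20),
               "fewer members")
})

test_that("the CNN adapter reports itself disabled without a backbone", {
  expect_error(cnnAdapter(list(), factor("AVB")), "plugin disabled")
  # a registered toy backbone flows through the same interface
  registerCnnBackbone("toy", function(images, labels) {
    list(predict = function(newImages)
      rep(as.character(labels)[1], length(newImages)))
  })
  h <- cnnAdapter(list(), factor("SA"), backbone = "toy")
  expect_equal(h$predict(list(1, 2)), c("SA", "SA"))
})
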