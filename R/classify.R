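# z-layout image encoding, K-means classification, macro-averaged
# evaluation and stratified cross-validation.

#' Truncate a segment to the largest square length
#'
#' Keeps the leading `side^2` samples where `side^2` is the largest perfect
#' square not exceeding the segment length; segments of ~3000 samples
#' truncate to 2916 (side 54).
#'
#' @param segment numeric amplitude sequence (length >= 4).
#' @return A list with `retained` (leading samples) and `side` (integer).
#' @examples
#' truncateSquare(numeric(3000))$side  # 54
#' @export
truncateSquare <- function(segment) {
  n <- length(segment)
  if (n < 4) stop("segment must contain at least 4 samples")
  side <- floor(sqrt(n))
  list(retained = segment[seq_len(side * side)], side = as.integer(side))
}

#' Encode a segment as a z-layout greyscale image
#'
#' Fills a square matrix row-major — first sample in the upper-left corner,
#' last in the lower-right — and maps amplitudes affinely from the
#' segment's \[min, max\] onto \[0, 255\]. A constant segment (zero
#' amplitude range) maps to uniform mid-grey 128. Because the mapping is
#' per-segment min-max, images are invariant under positive affine
#' amplitude transforms of the segment.
#'
#' @param segment numeric sequence whose length is a perfect square (apply
#'   [truncateSquare()] first).
#' @return A [SegmentImage-class].
#' @export
encodeZLayout <- function(segment) {
  n <- length(segment)
  side <- as.integer(round(sqrt(n)))
  if (side * side != n)
    stop("segment length ", n, " is not a perfect square; ",
         "apply truncateSquare() first")
  lo <- min(segment); hi <- max(segment)
  grey <- if (hi > lo) (segment - lo) / (hi - lo) * 255 else
    rep(128, n)
  new("SegmentImage",
      matrix = matrix(grey, nrow = side, ncol = side, byrow = TRUE),
      side = side, sourceLength = as.integer(n),
      ampRange = c(lo, hi))
}

# Min-max normalize one segment to [0, 1]; constant segments map to 0.5.
normalizeSegment <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi > lo) (v - lo) / (hi - lo) else rep(0.5, length(v))
}

#' K-means clustering by Lloyd iteration
#'
#' Partitions feature vectors into `k` clusters: centroids are initialized
#' as `k` distinct points drawn at random, then each point is assigned to
#' its closest centroid and centroids are recomputed until the assignment
#' reaches a fixed point (or `maxIter`). The within-cluster sum of squares
#' is non-increasing across iterations. A cluster left empty is re-seeded
#' from the point farthest from its centroid. `nstart` independent
#' initializations are run and the solution with the lowest within-cluster
#' sum of squares kept; everything is deterministic given `seed`.
#'
#' @param x numeric matrix, one row per point.
#' @param k number of clusters (1 <= k <= rows).
#' @param seed RNG seed.
#' @param nstart number of random restarts (default 25).
#' @param maxIter iteration cap per start (default 300).
#' @param tol convergence tolerance on total centroid movement
#'   (default 1e-6).
#' @return A list of class `"KMeansFit"`: `centroids` (k x p matrix),
#'   `cluster` (assignment per row), `wcss`, `iterations`.
#' @export
kmeansFit <- function(x, k, seed = 1L, nstart = 25L, maxIter = 300L,
                      tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("'k' must satisfy 1 <= k <= number of points")
  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      fit <- lloydOnce(x, k, maxIter, tol)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    class(best) <- "KMeansFit"
    best
  })
}

# squared Euclidean distances from every row of x to every centroid row
distToCentroids <- function(x, cen) {
  cross <- x %*% t(cen)
  sweep(sweep(-2 * cross, 2, rowSums(cen^2), `+`), 1, rowSums(x^2), `+`)
}

lloydOnce <- function(x, k, maxIter, tol) {
  n <- nrow(x)
  cen <- x[sample.int(n, k), , drop = FALSE]
  assign <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- distToCentroids(x, cen)
    newAssign <- max.col(-d2, ties.method = "first")
    newCen <- cen
    for (j in seq_len(k)) {
      members <- which(newAssign == j)
      if (length(members) == 0L) {
        # re-seed an empty cluster from the farthest point
        far <- which.max(d2[cbind(seq_len(n), newAssign)])
        newCen[j, ] <- x[far, ]
        newAssign[far] <- j
      } else {
        newCen[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    moved <- sum(sqrt(rowSums((newCen - cen)^2)))
    stable <- identical(newAssign, assign)
    cen <- newCen
    assign <- newAssign
    if ((stable && iter > 1L) || moved < tol || iter >= maxIter) break
  }
  d2 <- distToCentroids(x, cen)
  wcss <- sum(d2[cbind(seq_len(n), assign)])
  list(centroids = cen, cluster = assign, wcss = wcss, iterations = iter)
}

#' Assign new points to the nearest fitted centroid
#'
#' @param fit a `"KMeansFit"` from [kmeansFit()].
#' @param x matrix of points, one per row.
#' @return Integer cluster index per row.
#' @export
assignClusters <- function(fit, x) {
  d2 <- distToCentroids(as.matrix(x), fit$centroids)
  max.col(-d2, ties.method = "first")
}

#' Map unsupervised clusters to class labels by training majority
#'
#' Each cluster is mapped to the most frequent true label among its
#' training members; ties break toward the smallest class index (the order
#' of `levels(labels)`).
#'
#' @param cluster integer cluster assignment of the training points.
#' @param labels factor of true training labels.
#' @return Character vector: `mapping[j]` is the label of cluster `j`.
#' @export
mapClustersToLabels <- function(cluster, labels) {
  labels <- as.factor(labels)
  k <- max(cluster)
  vapply(seq_len(k), function(j) {
    members <- labels[cluster == j]
    if (length(members) == 0L) return(levels(labels)[1])
    counts <- table(members)
    names(counts)[which.max(counts)]  # which.max breaks ties to first level
  }, character(1))
}

#' F1 score from precision and recall
#'
#' The harmonic mean \eqn{2PR/(P+R)}, as used both per class and on the
#' macro-averaged precision and recall.
#'
#' @param precision,recall values in \[0, 1\].
#' @return The F1 score (NA if both inputs are zero or either is NA).
#' @examples
#' f1Score(0.78, 0.70)  # 0.7378...
#' @export
f1Score <- function(precision, recall) {
  ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Evaluate predictions with macro-averaged metrics
#'
#' Builds the confusion matrix (rows = actual, columns = predicted; the
#' diagonal holds the correctly predicted counts), derives one-vs-rest
#' TP/FP/FN/TN per class, and computes the macro-averaged accuracy,
#' precision and recall (equal-weight means of the per-class values) and
#' the F1 score as the harmonic mean of the macro precision and recall:
#' \deqn{F1 = 2 P R / (P + R).}
#' Per-class precision, recall and F1 are also reported. A class absent
#' from the truths has undefined recall; it is reported as NA and excluded
#' from the macro averages (recorded in the `excluded` attribute of the
#' per-class table).
#'
#' @param predictions predicted labels.
#' @param truths true labels (same length).
#' @param classes ordered class labels; defaults to the union of both.
#' @return An [EvaluationResult-class].
#' @examples
#' evaluateClassifier(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
evaluateClassifier <- function(predictions, truths, classes = NULL) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths))
    stop("'predictions' and 'truths' must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(predictions, truths)))
  total <- length(truths)
  conf <- table(factor(truths, levels = classes),
                factor(predictions, levels = classes))
  conf <- matrix(as.integer(conf), nrow = length(classes),
                 dimnames = list(actual = classes, predicted = classes))

  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- total - tp - fn - fp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & prec + rec > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  perClass <- data.frame(class = classes, tp = tp, fp = fp, fn = fn,
                         tn = tn, precision = prec, recall = rec, f1 = f1,
                         row.names = NULL)
  present <- rowSums(conf) > 0
  attr(perClass, "excluded") <- classes[!present]

  accs <- (tp + tn) / total
  macroAcc <- mean(accs[present])
  macroPrec <- mean(prec[present], na.rm = FALSE)
  macroRec <- mean(rec[present])
  if (is.na(macroPrec)) macroPrec <- mean(prec[present], na.rm = TRUE)
  macroF1 <- if (!is.na(macroPrec) && !is.na(macroRec) &&
                 macroPrec + macroRec > 0)
    2 * macroPrec * macroRec / (macroPrec + macroRec) else NA_real_
  new("EvaluationResult", classes = classes, confusion = conf,
      perClass = perClass,
      macro = c(accuracy = macroAcc, precision = macroPrec,
                recall = macroRec, f1 = macroF1),
      folds = data.frame())
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds
stratifiedFolds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in levels(as.factor(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", folds, ")")
    idx <- sample(idx)
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated K-means classification
#'
#' Stratified k-fold protocol: folds partition the dataset with class
#' balance preserved; for each fold, K-means is fitted on the training
#' segments (min-max normalized per segment), clusters are mapped to labels
#' by training majority, the held-out fold is predicted by nearest
#' centroid, and the macro metrics of the folds are averaged. The reported
#' confusion matrix is the sum over folds (every sample appears in exactly
#' one test fold).
#'
#' @param segments numeric matrix, one segment per row (e.g. from
#'   [makeSegmentDataset()]). Each row is truncated to the common largest
#'   square length and min-max normalized before clustering.
#' @param labels factor of true labels.
#' @param folds number of folds (default 10).
#' @param k number of clusters (default: number of classes).
#' @param seed RNG seed controlling fold assignment and K-means restarts.
#' @param nstart K-means restarts per fold (default 40).
#' @return An [EvaluationResult-class] whose `folds` slot holds the
#'   per-fold macro metrics and whose `macro` slot is their mean.
#' @export
crossValidate <- function(segments, labels, folds = 10L, k = NULL,
                          seed = 1L, nstart = 40L) {
  segments <- as.matrix(segments)
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (is.null(k)) k <- length(classes)
  sq <- truncateSquare(segments[1, ])
  keep <- seq_len(sq$side^2)
  feats <- t(apply(segments[, keep, drop = FALSE], 1, normalizeSegment))

  withSeed(seed, {
    foldId <- stratifiedFolds(labels, folds)
    foldSeeds <- sample.int(.Machine$integer.max - 1L, folds)
    perFold <- vector("list", folds)
    confSum <- NULL
    for (f in seq_len(folds)) {
      trainIdx <- which(foldId != f)
      testIdx <- which(foldId == f)
      fit <- kmeansFit(feats[trainIdx, , drop = FALSE], k,
                       seed = foldSeeds[f], nstart = nstart)
      mapping <- mapClustersToLabels(fit$cluster, labels[trainIdx])
      pred <- mapping[assignClusters(fit, feats[testIdx, , drop = FALSE])]
      ev <- evaluateClassifier(pred, as.character(labels[testIdx]), classes)
      m <- macroMetrics(ev)
      perFold[[f]] <- data.frame(fold = f, accuracy = m["accuracy"],
                                 precision = m["precision"],
                                 recall = m["recall"], f1 = m["f1"],
                                 row.names = NULL)
      confSum <- if (is.null(confSum)) confusionMatrix(ev) else
        confSum + confusionMatrix(ev)
    }
    foldTab <- do.call(rbind, perFold)
    macro <- c(accuracy = mean(foldTab$accuracy),
               precision = mean(foldTab$precision),
               recall = mean(foldTab$recall))
    macro["f1"] <- 2 * macro["precision"] * macro["recall"] /
      (macro["precision"] + macro["recall"])

    tp <- diag(confSum); fn <- rowSums(confSum) - tp
    fp <- colSums(confSum) - tp; tn <- sum(confSum) - tp - fn - fp
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
    rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
    f1 <- ifelse(!is.na(prec) & !is.na(rec) & prec + rec > 0,
                 2 * prec * rec / (prec + rec), NA_real_)
    perClass <- data.frame(class = classes, tp = tp, fp = fp, fn = fn,
                           tn = tn, precision = prec, recall = rec,
                           f1 = f1, row.names = NULL)
    new("EvaluationResult", classes = classes, confusion = confSum,
        perClass = perClass, macro = macro, folds = foldTab)
  })
}

#' Optional CNN transfer-learning adapter
#'
#' Interface point for an image-based transfer-learning classifier
#' (frozen-backbone head training followed by fine-tuning of the final
#' layers) over [encodeZLayout()] images. Training a CNN requires a
#' pretrained image backbone, which this package does not ship; the adapter
#' therefore reports itself disabled unless a backbone provider is
#' registered via `registerCnnBackbone()`. The K-means pipeline is fully
#' functional without it, and adapter predictions — when a backbone is
#' available — plug directly into [evaluateClassifier()].
#'
#' @param trainImages list of [SegmentImage-class] objects.
#' @param labels factor of training labels.
#' @param backbone backbone name requested (default `"inception_v3"`).
#' @return A classifier handle with a `predict` function.
#' @export
cnnAdapter <- function(trainImages, labels, backbone = "inception_v3") {
  provider <- cnnBackboneRegistry$providers[[backbone]]
  if (is.null(provider))
    stop("CNN plugin disabled: no pretrained backbone '", backbone,
         "' is registered; use the K-means classifier path instead")
  provider(trainImages, labels)
}

cnnBackboneRegistry <- new.env(parent = emptyenv())
cnnBackboneRegistry$providers <- list()

#' @rdname cnnAdapter
#' @param name backbone name to register.
#' @param provider function(trainImages, labels) returning a classifier
#'   handle with a `predict` function.
#' @export
registerCnnBackbone <- function(name, provider) {
  stopifnot(is.function(provider))
  cnnBackboneRegistry$providers[[name]] <- provider
  invisible(name)
}
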