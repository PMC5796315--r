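#' @import methods
NULL

#' ECGRecord: a uniformly sampled electrocardiogram trace
#'
#' Container for a single-channel ECG signal. Amplitudes are stored in
#' millivolts after dividing out any acquisition gain; time is implicit in
#' the sampling rate and start offset.
#'
#' @slot samples numeric vector of amplitudes (mV), finite, length >= 1.
#' @slot fs sampling rate in Hz (> 0); zebrafish recordings are typically
#'   digitized at 1000 Hz.
#' @slot channelId channel label.
#' @slot t0 start-time offset in seconds.
#' @slot meta free-form list of provenance key/value pairs.
#'
#' @seealso [ECGRecord()] for construction, [readRecord()] to read from disk.
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(
    samples   = "numeric",
    fs        = "numeric",
    channelId = "character",
    t0        = "numeric",
    meta      = "list"
  ),
  prototype(fs = 1000, channelId = "ch1", t0 = 0, meta = list())
)

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive finite number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "'samples' must contain at least one sample")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  if (length(object@channelId) != 1L)
    msg <- c(msg, "'channelId' must be a single label")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param samples numeric vector of amplitudes in mV.
#' @param fs sampling rate in Hz (default 1000).
#' @param channelId channel label.
#' @param t0 start-time offset in seconds.
#' @param meta list of provenance metadata.
#' @return An [ECGRecord-class] object.
#' @examples
#' rec <- ECGRecord(sin(2 * pi * 2 * seq(0, 1, by = 1e-3)), fs = 1000)
#' nSamples(rec)
#' @export
ECGRecord <- function(samples, fs = 1000, channelId = "ch1", t0 = 0,
                      meta = list()) {
  new("ECGRecord", samples = as.numeric(samples), fs = as.numeric(fs),
      channelId = as.character(channelId), t0 = as.numeric(t0), meta = meta)
}

#' ECGGroundTruth: generator-side annotations for a synthetic record
#'
#' Per-beat true fiducial sample indices (1-based) emitted by
#' [generateECG()], plus pause intervals created by sinus-arrest injection
#' and any ST-segment offset. Beats whose QRS/T were dropped
#' (atrioventricular block) keep their P index and carry `dropped = TRUE`
#' with NA QRS/T indices.
#'
#' @slot beats data.frame with columns `beat`, `p`, `q`, `r`, `s`, `t`
#'   (sample indices, NA where the wave was dropped) and `dropped` (logical).
#' @slot pauses data.frame with columns `start`, `end` (sample indices of
#'   injected sinus pauses; zero rows if none).
#' @slot stOffset numeric, constant ST-segment elevation injected (mV).
#'
#' @exportClass ECGGroundTruth
setClass("ECGGroundTruth",
  representation(beats = "data.frame", pauses = "data.frame",
                 stOffset = "numeric"),
  prototype(pauses = data.frame(start = integer(), end = integer()),
            stOffset = 0)
)

setValidity("ECGGroundTruth", function(object) {
  b <- object@beats
  need <- c("beat", "p", "q", "r", "s", "t", "dropped")
  if (!all(need %in% names(b)))
    return(sprintf("'beats' must contain columns %s",
                   paste(need, collapse = ", ")))
  r <- b$r[!is.na(b$r)]
  if (is.unsorted(r, strictly = TRUE))
    return("true R indices must be strictly increasing")
  ok <- !b$dropped
  if (any(ok & (is.na(b$p) | is.na(b$q) | is.na(b$r) | is.na(b$s) |
                is.na(b$t))))
    return("non-dropped beats must have all five fiducials")
  TRUE
})

#' SegmentImage: z-layout greyscale encoding of an ECG segment
#'
#' A square greyscale matrix produced by [encodeZLayout()]: the segment is
#' written row-major, first sample in the upper-left corner, last sample in
#' the lower-right, with amplitudes mapped affinely onto \[0, 255\].
#'
#' @slot matrix side x side numeric matrix with values in \[0, 255\].
#' @slot side image side length; `side^2` equals the samples retained.
#' @slot sourceLength number of samples encoded.
#' @slot ampRange length-2 numeric, the \[min, max\] amplitude bounds (mV)
#'   of the affine greyscale mapping.
#'
#' @exportClass SegmentImage
setClass("SegmentImage",
  representation(matrix = "matrix", side = "integer",
                 sourceLength = "integer", ampRange = "numeric")
)

setValidity("SegmentImage", function(object) {
  msg <- character()
  if (!identical(dim(object@matrix), c(object@side, object@side)))
    msg <- c(msg, "'matrix' must be side x side")
  if (object@side^2 != object@sourceLength)
    msg <- c(msg, "side^2 must equal sourceLength")
  v <- object@matrix
  if (any(v < -1e-9 | v > 255 + 1e-9))
    msg <- c(msg, "greyscale values must lie in [0, 255]")
  if (length(object@ampRange) != 2L)
    msg <- c(msg, "'ampRange' must have length 2")
  if (length(msg)) msg else TRUE
})

#' EvaluationResult: confusion matrix and macro-averaged metrics
#'
#' Classification scores for a multi-class evaluation: the confusion matrix
#' (rows = actual, columns = predicted), per-class one-vs-rest counts and
#' precision/recall/F1, and the macro-averaged accuracy, precision, recall
#' and F1 (the F1 computed from the macro precision and recall).
#'
#' @slot classes ordered class labels.
#' @slot confusion integer matrix, rows actual x columns predicted.
#' @slot perClass data.frame with columns `class`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @slot macro named numeric: `accuracy`, `precision`, `recall`, `f1`.
#' @slot folds data.frame of per-fold macro metrics (zero rows when the
#'   result is not cross-validated).
#'
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(classes = "character", confusion = "matrix",
                 perClass = "data.frame", macro = "numeric",
                 folds = "data.frame"),
  prototype(folds = data.frame())
)

setValidity("EvaluationResult", function(object) {
  k <- length(object@classes)
  if (!identical(dim(object@confusion), c(k, k)))
    return("'confusion' must be k x k for k classes")
  if (any(object@confusion < 0))
    return("confusion counts must be non-negative")
  m <- object@macro
  if (!all(c("accuracy", "precision", "recall", "f1") %in% names(m)))
    return("'macro' must contain accuracy, precision, recall, f1")
  if (any(is.finite(m) & (m < -1e-9 | m > 1 + 1e-9)))
    return("macro metrics must lie in [0, 1]")
  TRUE
})

# ---- generics ----------------------------------------------------------

#' @rdname ECGRecord-class
#' @param object,x an object.
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))

#' @rdname ECGRecord-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname ECGRecord-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname ECGRecord-class
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname ECGRecord-class
#' @export
setMethod("ecgSamples", "ECGRecord", function(x) x@samples)

#' @rdname ECGRecord-class
#' @export
setMethod("samplingRate", "ECGRecord", function(x) x@fs)

#' @rdname ECGRecord-class
#' @export
setMethod("nSamples", "ECGRecord", function(x) length(x@samples))

#' @rdname ECGRecord-class
#' @export
setMethod("recordDuration", "ECGRecord",
          function(x) length(x@samples) / x@fs)

#' @rdname ECGRecord-class
#' @export
setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord '%s': %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              object@channelId, length(object@samples), object@fs,
              length(object@samples) / object@fs, object@t0))
  rng <- range(object@samples)
  cat(sprintf("  amplitude range [%.4g, %.4g] mV\n", rng[1], rng[2]))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname ECGGroundTruth-class
#' @param object an `ECGGroundTruth`.
#' @export
setMethod("show", "ECGGroundTruth", function(object) {
  b <- object@beats
  cat(sprintf("ECGGroundTruth: %d beats (%d dropped), %d pause(s)",
              nrow(b), sum(b$dropped), nrow(object@pauses)))
  if (object@stOffset != 0)
    cat(sprintf(", ST offset %+.3g mV", object@stOffset))
  cat("\n")
  invisible(NULL)
})

#' @rdname ECGGroundTruth-class
#' @param x an `ECGGroundTruth`.
#' @export
setGeneric("truthBeats", function(x) standardGeneric("truthBeats"))

#' @rdname ECGGroundTruth-class
#' @export
setMethod("truthBeats", "ECGGroundTruth", function(x) x@beats)

#' @rdname ECGGroundTruth-class
#' @export
setGeneric("truthRPeaks", function(x) standardGeneric("truthRPeaks"))

#' @rdname ECGGroundTruth-class
#' @export
setMethod("truthRPeaks", "ECGGroundTruth", function(x) {
  r <- x@beats$r
  as.integer(r[!is.na(r)])
})

#' @rdname SegmentImage-class
#' @param object a `SegmentImage`.
#' @export
setMethod("show", "SegmentImage", function(object) {
  cat(sprintf(
    "SegmentImage: %d x %d greyscale (z-layout of %d samples), mV range [%.4g, %.4g]\n",
    object@side, object@side, object@sourceLength,
    object@ampRange[1], object@ampRange[2]))
  invisible(NULL)
})

#' @rdname SegmentImage-class
#' @param x a `SegmentImage`.
#' @export
setGeneric("imageMatrix", function(x) standardGeneric("imageMatrix"))

#' @rdname SegmentImage-class
#' @export
setMethod("imageMatrix", "SegmentImage", function(x) x@matrix)

#' @rdname EvaluationResult-class
#' @param x an `EvaluationResult`.
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname EvaluationResult-class
#' @export
setMethod("confusionMatrix", "EvaluationResult", function(x) x@confusion)

#' @rdname EvaluationResult-class
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname EvaluationResult-class
#' @export
setMethod("macroMetrics", "EvaluationResult", function(x) x@macro)

#' @rdname EvaluationResult-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname EvaluationResult-class
#' @export
setMethod("perClassMetrics", "EvaluationResult", function(x) x@perClass)

#' @rdname EvaluationResult-class
#' @param object an `EvaluationResult`.
#' @export
setMethod("show", "EvaluationResult", function(object) {
  cat("EvaluationResult over classes:",
      paste(object@classes, collapse = ", "), "\n")
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(object@confusion)
  pc <- object@perClass
  cat("Per-class metrics:\n")
  print(data.frame(class = pc$class,
                   precision = round(pc$precision, 4),
                   recall = round(pc$recall, 4),
                   f1 = round(pc$f1, 4)), row.names = FALSE)
  m <- object@macro
  cat(sprintf(
    "Macro: accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
    m["accuracy"], m["precision"], m["recall"], m["f1"]))
  if (nrow(object@folds))
    cat(sprintf("Averaged over %d cross-validation folds\n",
                nrow(object@folds)))
  invisible(NULL)
})
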