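#' @include AllClasses.R
NULL

#' Accessors for video and result containers
#'
#' \code{frames} returns the list of frame matrices; \code{fps} the frame
#' rate; \code{pixelScaleUm} the micrometres-per-pixel scale; \code{nFrames}
#' the frame count; \code{frameDims} the (rows, cols) frame size.
#'
#' @param x a \linkS4class{FrameSequence}, \linkS4class{GroundTruth} or
#'   \linkS4class{TrackSet}.
#' @return the slot value.
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("pixelScaleUm", function(x) standardGeneric("pixelScaleUm"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameDims", function(x) standardGeneric("frameDims"))

#' @rdname accessors
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("fps", "FrameSequence", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("fps", "GroundTruth", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("pixelScaleUm", "FrameSequence", function(x) x@pixelScaleUm)

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("frameDims", "FrameSequence", function(x) dim(x@frames[[1L]]))

#' Ground-truth track table
#'
#' Long-format data.frame of the annotated objects (one row per object per
#' frame): columns id, class, frame, x, y, area.
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return data.frame.
#' @export
setGeneric("groundTruthTable", function(x) standardGeneric("groundTruthTable"))

#' @rdname groundTruthTable
#' @export
setMethod("groundTruthTable", "GroundTruth", function(x) x@tracks)

#' Evaluation metrics from confusion counts
#'
#' Percent-scale detection metrics: \code{accuracy} = 100 (TP + TN) /
#' (TP + TN + FP + FN); \code{sensitivity} = 100 TP / (TP + FN);
#' \code{specificity} = 100 TN / (TN + FP). A zero denominator yields
#' \code{NA_real_} (the metric is undefined, not 0).
#'
#' @param x a \linkS4class{ConfusionCounts}.
#' @return percentage in [0, 100], or NA when undefined.
#' @rdname metrics
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname metrics
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname metrics
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1L]])
  cat("FrameSequence:", length(object@frames), "frames of", d[2L], "x", d[1L],
      "px,", object@fps, "fps,", object@pixelScaleUm, "um/px\n")
})

setMethod("show", "GroundTruth", function(object) {
  tr <- object@tracks
  ids <- unique(tr[, c("id", "class")])
  cat("GroundTruth:", nrow(ids), "objects (",
      sum(ids$class == "motile"), "motile,",
      sum(ids$class == "immotile"), "immotile,",
      sum(ids$class == "debris"), "debris ) over",
      if (nrow(tr)) max(tr$frame) else 0L, "frames\n")
})

setMethod("show", "MixtureState", function(object) {
  cat("MixtureState:", object@dims[2L], "x", object@dims[1L], "px,",
      ncol(object@weight), "Gaussians/pixel,",
      object@frameCount, "frames consumed\n")
})

setMethod("show", "TrackSet", function(object) {
  st <- vapply(object@tracks, `[[`, character(1L), "status")
  cat("TrackSet:", length(object@tracks), "tracks (",
      sum(st == "active"), "active,", sum(st == "lost"), "lost ), stride",
      object@stride, "\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP =", object@TP, " TN =", object@TN,
      " FP =", object@FP, " FN =", object@FN, "\n")
})

setMethod("show", "SampleSummary", function(object) {
  tot <- object@nImmotile + object@nFast + object@nSlow
  cat("SampleSummary:", tot, "sperm |", object@nFast, "fast progressive,",
      object@nSlow, "slow progressive,", object@nImmotile, "immotile\n")
  cat("  motile fraction", sprintf("%.3f", object@motileFraction),
      "->", object@classification, "\n")
})
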