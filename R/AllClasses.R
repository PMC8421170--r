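#' @import methods
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

## Shared coordinate convention: pixels are 0-based, x = column index,
## y = row index, origin at the top-left pixel centre. Frames are stored as
## integer matrices indexed [y + 1, x + 1] with intensities in 0..255.

#' FrameSequence: an ordered grayscale video
#'
#' Ordered list of 8-bit grayscale frames together with the acquisition frame
#' rate and the pixel-to-micrometre scale. All downstream stages (background
#' modelling, detection, tracking, motility) consume this container.
#'
#' @slot frames list of integer matrices (rows x cols, values 0..255), all of
#'   identical dimension.
#' @slot fps frames per second (> 0).
#' @slot pixelScaleUm micrometres per pixel (> 0). Default used throughout the
#'   package is 0.2 um/px, appropriate for a 640x480 camera at x400
#'   magnification; it is always overridable because every velocity scales
#'   linearly with it.
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "list", fps = "numeric", pixelScaleUm = "numeric"))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) == 0L) return("frames must contain at least one frame")
  d <- dim(object@frames[[1L]])
  if (is.null(d)) return("frames must be matrices")
  for (f in object@frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      return("all frames must be matrices of identical dimensions")
  }
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  if (length(object@pixelScaleUm) != 1L || !is.finite(object@pixelScaleUm) ||
      object@pixelScaleUm <= 0)
    return("pixelScaleUm must be a single positive number")
  TRUE
})

#' GroundTruth: per-frame object annotations for a synthetic video
#'
#' Long-format table of object positions with one row per object per frame in
#' which the object is rendered. Classes are \code{motile}, \code{immotile}
#' and \code{debris}.
#'
#' @slot tracks data.frame with columns \code{id} (integer), \code{class}
#'   (character), \code{frame} (integer, 1-based), \code{x}, \code{y}
#'   (0-based pixel centre coordinates) and \code{area} (rendered pixel
#'   count).
#' @slot fps frames per second of the generating video.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(tracks = "data.frame", fps = "numeric"))

setValidity("GroundTruth", function(object) {
  req <- c("id", "class", "frame", "x", "y", "area")
  if (!all(req %in% names(object@tracks)))
    return(paste("tracks must have columns", paste(req, collapse = ", ")))
  if (nrow(object@tracks) &&
      !all(object@tracks$class %in% c("motile", "immotile", "debris")))
    return("class must be motile, immotile or debris")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a single positive number")
  TRUE
})

#' SynthConfig: parameters of the synthetic video generator
#'
#' @slot width,height frame size in pixels.
#' @slot nFrames number of frames.
#' @slot fps frames per second.
#' @slot nMotile,nImmotile,nDebris object counts.
#' @slot headSemiAxesRange length-2 numeric, min/max of the head ellipse
#'   semi-axes in pixels (semi-minor drawn between min and semi-major).
#' @slot speedRange length-2 numeric, min/max motile speed in px/frame.
#' @slot debrisAreaMax maximum debris blob area in pixel^2; must stay below
#'   the detection minimum-area rule (150 px^2).
#' @slot backgroundLevel,headLevel 8-bit intensities (heads bright on a dark
#'   background).
#' @slot noiseSigma standard deviation of additive Gaussian sensor noise
#'   (intensity units).
#' @slot border \code{"exit"} (objects leave permanently) or
#'   \code{"reflect"} (objects bounce off frame borders).
#' @slot headingJitterSd per-frame heading jitter (radians); 0 disables.
#' @slot illuminationGradient logical; add a mild horizontal illumination
#'   ramp for robustness experiments.
#' @slot motileInit optional data.frame (x, y, speed, heading) overriding the
#'   randomly drawn motile initial states; zero rows means draw randomly.
#' @slot seed integer RNG seed; identical configs give bit-identical output.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(width = "integer", height = "integer", nFrames = "integer",
    fps = "numeric", nMotile = "integer", nImmotile = "integer",
    nDebris = "integer", headSemiAxesRange = "numeric", speedRange = "numeric",
    debrisAreaMax = "numeric", backgroundLevel = "numeric",
    headLevel = "numeric", noiseSigma = "numeric", border = "character",
    headingJitterSd = "numeric", illuminationGradient = "logical",
    motileInit = "data.frame", seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@width < 1L || object@height < 1L || object@nFrames < 1L)
    return("width, height and nFrames must be >= 1")
  if (object@nMotile < 0L || object@nImmotile < 0L || object@nDebris < 0L)
    return("object counts must be >= 0")
  if (object@debrisAreaMax >= 150)
    return("debrisAreaMax must be < 150 (the detection minimum-area rule)")
  if (object@headLevel == object@backgroundLevel)
    return("headLevel must differ from backgroundLevel")
  if (length(object@speedRange) != 2L || any(object@speedRange < 0))
    return("speedRange must be two non-negative values")
  if (length(object@headSemiAxesRange) != 2L ||
      any(object@headSemiAxesRange <= 0))
    return("headSemiAxesRange must be two positive values")
  if (diff(object@headSemiAxesRange) < 0 || diff(object@speedRange) < 0)
    return("ranges must be ordered (min, max)")
  if (2 * object@headSemiAxesRange[2L] >= min(object@width, object@height))
    return("head larger than frame: impossible geometry")
  if (!object@border %in% c("exit", "reflect"))
    return("border must be 'exit' or 'reflect'")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (nrow(object@motileInit) &&
      !all(c("x", "y", "speed", "heading") %in% names(object@motileInit)))
    return("motileInit needs columns x, y, speed, heading")
  TRUE
})

#' BackgroundParams: adaptive Gaussian-mixture background model parameters
#'
#' @slot bgt background ratio threshold in (0, 1], or \code{NA_real_} for
#'   automatic per-sample optimization over the grid.
#' @slot K Gaussians per pixel (>= 2).
#' @slot alpha weight learning rate.
#' @slot lambda match threshold in standard deviations.
#' @slot initialVariance variance given to newly created components.
#' @slot varianceFloor lower bound kept on all component variances.
#' @slot weightFloor weight given to replacement components.
#' @slot adaptiveStart logical; if TRUE the learning rate follows a 1/t
#'   schedule while t < 1/alpha, so that background revealed behind objects
#'   present in the bootstrap frame is absorbed quickly (no ghost trails).
#' @slot burnInFrames frames used to learn the background before any
#'   detection is trusted.
#' @slot grid BG_T candidate grid for the automatic optimizer.
#' @exportClass BackgroundParams
setClass("BackgroundParams",
  representation(bgt = "numeric", K = "integer", alpha = "numeric",
    lambda = "numeric", initialVariance = "numeric", varianceFloor = "numeric",
    weightFloor = "numeric", adaptiveStart = "logical",
    burnInFrames = "integer", grid = "numeric"))

setValidity("BackgroundParams", function(object) {
  if (!is.na(object@bgt) && (object@bgt <= 0 || object@bgt > 1))
    return("bgt must lie in (0, 1] or be NA for automatic optimization")
  if (object@K < 2L) return("K must be >= 2")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@varianceFloor <= 0) return("varianceFloor must be > 0")
  if (object@initialVariance < object@varianceFloor)
    return("initialVariance must be >= varianceFloor")
  if (object@weightFloor <= 0 || object@weightFloor >= 1)
    return("weightFloor must be in (0,1)")
  if (object@burnInFrames < 1L) return("burnInFrames must be >= 1")
  if (any(object@grid <= 0 | object@grid > 1)) return("grid values in (0,1]")
  TRUE
})

#' MixtureState: per-pixel Gaussian mixture background model
#'
#' Flat storage of the per-pixel mixtures: each slot matrix has one row per
#' pixel (column-major frame order) and one column per mixture component.
#'
#' @slot weight,mean,var npix x K numeric matrices of component weights,
#'   means and variances. Weights sum to 1 within each row.
#' @slot dims frame dimensions (rows, cols).
#' @slot frameCount number of frames consumed so far.
#' @exportClass MixtureState
setClass("MixtureState",
  representation(weight = "matrix", mean = "matrix", var = "matrix",
    dims = "integer", frameCount = "integer"))

setValidity("MixtureState", function(object) {
  if (!all(dim(object@weight) == dim(object@mean)) ||
      !all(dim(object@weight) == dim(object@var)))
    return("weight, mean and var must have identical dimensions")
  if (nrow(object@weight) != prod(object@dims))
    return("state rows must equal the pixel count")
  if (any(object@var <= 0)) return("variances must be positive")
  s <- rowSums(object@weight)
  if (max(abs(s - 1)) > 1e-8) return("per-pixel weights must sum to 1")
  TRUE
})

#' MorphologyParams: structuring element for mask cleaning
#'
#' @slot seShape one of \code{"disk"}, \code{"line"}, \code{"square"}.
#' @slot seRadius radius in pixels (>= 1); the structuring element spans
#'   \code{2 * seRadius + 1} pixels.
#' @exportClass MorphologyParams
setClass("MorphologyParams",
  representation(seShape = "character", seRadius = "integer"))

setValidity("MorphologyParams", function(object) {
  if (!object@seShape %in% c("disk", "line", "square"))
    return("seShape must be disk, line or square")
  if (object@seRadius < 1L) return("seRadius must be >= 1")
  TRUE
})

#' TrackingParams: association gates and sampling stride
#'
#' @slot tDis Euclidean distance gate in pixels between consecutive sampled
#'   observations of the same sperm (default 125).
#' @slot tSize maximum ratio of head areas between consecutive observations
#'   (default 1.2).
#' @slot stride frames between sampled observations (default 10).
#' @slot scaleGateWithStride logical; if TRUE the distance gate scales
#'   linearly when the stride is changed from 10.
#' @exportClass TrackingParams
setClass("TrackingParams",
  representation(tDis = "numeric", tSize = "numeric", stride = "integer",
    scaleGateWithStride = "logical"))

setValidity("TrackingParams", function(object) {
  if (object@tDis <= 0) return("tDis must be > 0")
  if (object@tSize < 1) return("tSize must be >= 1")
  if (object@stride < 1L) return("stride must be >= 1")
  TRUE
})

#' TrackSet: recovered sperm tracks for one video
#'
#' @slot tracks list of per-track lists with elements \code{id},
#'   \code{frames}, \code{x}, \code{y}, \code{area} (parallel vectors) and
#'   \code{status} (\code{"active"} or \code{"lost"}).
#' @slot fps,pixelScaleUm acquisition scale carried from the FrameSequence.
#' @slot stride sampled-frame stride used during association.
#' @slot nextId next unused track id.
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "list", fps = "numeric", pixelScaleUm = "numeric",
    stride = "integer", nextId = "integer"))

#' ConfusionCounts: detection-evaluation tallies
#'
#' @slot TP,TN,FP,FN non-negative integer counts. Positives are motile sperm;
#'   negatives are immotile cells and debris.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(TP = "integer", TN = "integer", FP = "integer",
    FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@TP, object@TN, object@FP, object@FN) < 0L))
    return("counts must be >= 0")
  TRUE
})

#' SampleSummary: sample-level motility result
#'
#' @slot nImmotile,nFast,nSlow sperm counts per WHO class.
#' @slot meanVelocityFast,sdVelocityFast,meanVelocitySlow,sdVelocitySlow
#'   within-class velocity statistics in um/s (NA when a class is empty).
#' @slot motileFraction (nFast + nSlow) / total.
#' @slot classification \code{"normal"} or \code{"abnormal"}.
#' @exportClass SampleSummary
setClass("SampleSummary",
  representation(nImmotile = "integer", nFast = "integer", nSlow = "integer",
    meanVelocityFast = "numeric", sdVelocityFast = "numeric",
    meanVelocitySlow = "numeric", sdVelocitySlow = "numeric",
    motileFraction = "numeric", classification = "character"))
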