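#' @include AllClasses.R
NULL

#' Confusion counts constructor
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(TP = 0L, TN = 0L, FP = 0L, FN = 0L) {
  new("ConfusionCounts", TP = as.integer(TP), TN = as.integer(TN),
      FP = as.integer(FP), FN = as.integer(FN))
}

#' Score one frame's detections against ground truth
#'
#' Greedy nearest matching of detections to the ground-truth objects present
#' in the frame, within a distance gate (candidates sorted by distance, ties
#' by ground-truth id then detection order, each side used once). Motile
#' objects are the positives: TP = detections matched to motile objects,
#' FN = motile objects left unmatched, FP = detections matched to nothing or
#' to debris, TN = immotile objects and debris with no detection on them.
#'
#' @param detections data.frame from \code{\link{detectFrame}}.
#' @param gt a \linkS4class{GroundTruth} covering \code{frameIndex}.
#' @param frameIndex the frame to score.
#' @param gatePx matching radius in pixels (default 20).
#' @return a \linkS4class{ConfusionCounts}.
#' @export
matchToGroundTruth <- function(detections, gt, frameIndex, gatePx = 20) {
  stopifnot(is(gt, "GroundTruth"))
  tr <- gt@tracks
  if (!frameIndex %in% tr$frame)
    stop("ground truth does not cover frame ", frameIndex)
  obj <- tr[tr$frame == frameIndex, , drop = FALSE]
  ng <- nrow(obj); nd <- nrow(detections)
  matchedG <- integer(0); matchedD <- integer(0)
  if (ng && nd) {
    cand <- expand.grid(g = seq_len(ng), d = seq_len(nd))
    cand$dist <- sqrt((obj$x[cand$g] - detections$x[cand$d])^2 +
                      (obj$y[cand$g] - detections$y[cand$d])^2)
    cand <- cand[cand$dist <= gatePx, , drop = FALSE]
    cand <- cand[order(cand$dist, obj$id[cand$g], cand$d), , drop = FALSE]
    usedG <- logical(ng); usedD <- logical(nd)
    for (k in seq_len(nrow(cand))) {
      g <- cand$g[k]; d <- cand$d[k]
      if (!usedG[g] && !usedD[d]) {
        usedG[g] <- TRUE; usedD[d] <- TRUE
        matchedG <- c(matchedG, g); matchedD <- c(matchedD, d)
      }
    }
  }
  cls <- obj$class
  TP <- sum(cls[matchedG] == "motile")
  FP <- nd - TP
  FN <- sum(cls == "motile") - TP
  negUnmatched <- setdiff(which(cls != "motile"), matchedG)
  TN <- length(negUnmatched)
  confusionCounts(TP, TN, FP, FN)
}

#' @rdname metrics
#' @export
setMethod("accuracy", "ConfusionCounts", function(x) {
  den <- x@TP + x@TN + x@FP + x@FN
  if (den == 0L) return(NA_real_)
  100 * (x@TP + x@TN) / den
})

#' @rdname metrics
#' @export
setMethod("sensitivity", "ConfusionCounts", function(x) {
  den <- x@TP + x@FN
  if (den == 0L) return(NA_real_)
  100 * x@TP / den
})

#' @rdname metrics
#' @export
setMethod("specificity", "ConfusionCounts", function(x) {
  den <- x@TN + x@FP
  if (den == 0L) return(NA_real_)
  100 * x@TN / den
})

#' Combine confusion counts
#'
#' Pools TP/TN/FP/FN over frames or samples by summation.
#'
#' @param ... \linkS4class{ConfusionCounts} objects.
#' @return a pooled \linkS4class{ConfusionCounts}.
#' @export
poolCounts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1L]]) && !is(cs[[1L]],
      "ConfusionCounts")) cs <- cs[[1L]]
  confusionCounts(sum(vapply(cs, slot, 1L, "TP")),
                  sum(vapply(cs, slot, 1L, "TN")),
                  sum(vapply(cs, slot, 1L, "FP")),
                  sum(vapply(cs, slot, 1L, "FN")))
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize per-sample metrics as mean and standard deviation
#'
#' Arithmetic mean and population standard deviation (divisor n) of each
#' metric column over the samples; the sample (divisor n - 1) standard
#' deviation is available via \code{sampleSd = TRUE}. Values are returned at
#' full precision — rounding to the reporting precision (one decimal for
#' means, two for standard deviations) is a presentation choice left to the
#' caller.
#'
#' @param perSample data.frame with numeric columns \code{accuracy},
#'   \code{sensitivity}, \code{specificity} (percent scale), one row per
#'   sample; NA entries (undefined metrics) are dropped per metric.
#' @param sampleSd use the n - 1 divisor instead of n.
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd}.
#' @export
summarizePerformance <- function(perSample, sampleSd = FALSE) {
  stopifnot(nrow(perSample) >= 1L)
  metrics <- c("accuracy", "sensitivity", "specificity")
  stopifnot(all(metrics %in% names(perSample)))
  rows <- lapply(metrics, function(m) {
    v <- perSample[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m, mean = mean(v),
               sd = if (sampleSd) {
                 if (length(v) >= 2L) sd(v) else 0
               } else popSd(v))
  })
  do.call(rbind, rows)
}

#' Bundled worked example: ten-sample detection scores
#'
#' Per-sample detection accuracy, sensitivity and specificity (percent) for
#' three segmentation approaches — a GMM-based motile-head detector
#' (\code{"proposed"}) and adaptive- and global-thresholding baselines —
#' evaluated on ten human semen samples, together with each sample's motile
#' and immotile sperm counts. Used as input to
#' \code{\link{summarizePerformance}} in the package's worked examples.
#'
#' @return data.frame with columns \code{sample}, \code{motile},
#'   \code{immotile}, \code{method}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
detectionScoresExample <- function() {
  read.csv(system.file("extdata", "detection_scores_ten_samples.csv",
                       package = "SpermMotility"), stringsAsFactors = FALSE)
}

#' Bundled worked example: ten-sample motility counts
#'
#' Per-sample WHO-class counts (immotile, fast progressive, slow
#' progressive) with within-class velocity statistics and the reported
#' normal/abnormal call, for ten human semen samples. Used as input to
#' \code{\link{classifySample}} in the package's worked examples.
#'
#' @return data.frame with columns \code{sample}, \code{immotile},
#'   \code{fast}, \code{fast_mean_velocity}, \code{fast_sd}, \code{slow},
#'   \code{slow_mean_velocity}, \code{slow_sd}, \code{reported_class}.
#' @export
motilityCountsExample <- function() {
  read.csv(system.file("extdata", "motility_counts_ten_samples.csv",
                       package = "SpermMotility"), stringsAsFactors = FALSE)
}
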