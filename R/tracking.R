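#' @include AllClasses.R
NULL

#' Tracking parameters
#'
#' Gates used to link detections across sampled frames: a Euclidean distance
#' gate (the same sperm must not move more than \code{tDis} pixels between
#' consecutive sampled observations) and a size-similarity gate (head areas
#' must agree within a factor \code{tSize}).
#'
#' @param tDis distance gate in pixels (default 125, calibrated for a
#'   10-frame stride).
#' @param tSize maximum area ratio between consecutive observations
#'   (default 1.2).
#' @param stride association runs on every \code{stride}-th frame
#'   (default 10); the background model still consumes every frame.
#' @param scaleGateWithStride if TRUE, \code{tDis} is scaled by
#'   \code{stride / 10} so the gate tracks the sampling interval.
#' @return a \linkS4class{TrackingParams}.
#' @export
trackingParams <- function(tDis = 125, tSize = 1.2, stride = 10L,
                           scaleGateWithStride = FALSE) {
  p <- new("TrackingParams", tDis = as.numeric(tDis),
           tSize = as.numeric(tSize), stride = as.integer(stride),
           scaleGateWithStride = scaleGateWithStride)
  if (scaleGateWithStride) p@tDis <- p@tDis * p@stride / 10
  p
}

#' Euclidean distance between two centroids
#'
#' @param sc,sp length-2 numeric vectors (x, y) in pixels.
#' @return distance in pixels.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))   # 5
#' @export
euclideanDistance <- function(sc, sp) {
  stopifnot(all(is.finite(sc)), all(is.finite(sp)))
  sqrt(sum((sc - sp)^2))
}

#' Size similarity gate
#'
#' Returns 1 when two head areas agree within a factor \code{tSize}
#' (\code{max(a1, a2) / min(a1, a2) <= tSize}), else 0. Symmetric in its two
#' area arguments.
#'
#' @param szp,szc head areas (px^2) in the previous and current frame (> 0).
#' @param tSize maximum allowed ratio (default 1.2).
#' @return 0 or 1.
#' @examples
#' sizeSimilarity(120, 100)   # ratio 1.2 -> 1
#' sizeSimilarity(200, 100)   # ratio 2.0 -> 0
#' @export
sizeSimilarity <- function(szp, szc, tSize = 1.2) {
  if (any(szp <= 0) || any(szc <= 0)) stop("areas must be positive")
  as.integer(pmax(szp, szc) / pmin(szp, szc) <= tSize)
}

lastObs <- function(trk) {
  n <- length(trk$frames)
  c(x = trk$x[n], y = trk$y[n], area = trk$area[n])
}

#' Associate tracks with the detections of one sampled frame
#'
#' Greedy one-to-one matching: every (active track, detection) pair passing
#' both gates (distance \code{<= tDis} and area ratio \code{<= tSize}) is a
#' candidate; candidates are consumed in order of increasing distance (ties:
#' smaller area ratio, then lower track id, then detection order), each
#' track and detection used at most once.
#'
#' @param activeTracks list of track records (elements \code{id},
#'   \code{frames}, \code{x}, \code{y}, \code{area}).
#' @param detections data.frame from \code{\link{detectFrame}} (columns
#'   \code{x}, \code{y}, \code{ellipticalArea}).
#' @param params a \linkS4class{TrackingParams}.
#' @return list with \code{matches} (data.frame \code{trackPos},
#'   \code{detection}: positions in the two inputs), \code{unmatchedTracks}
#'   and \code{unmatchedDetections} (integer position vectors).
#' @export
associateDetections <- function(activeTracks, detections, params) {
  nt <- length(activeTracks); nd <- nrow(detections)
  noMatch <- data.frame(trackPos = integer(0), detection = integer(0))
  if (nt == 0L || nd == 0L)
    return(list(matches = noMatch, unmatchedTracks = seq_len(nt),
                unmatchedDetections = seq_len(nd)))
  prev <- t(vapply(activeTracks, lastObs, numeric(3L)))
  cand <- expand.grid(trackPos = seq_len(nt), detection = seq_len(nd))
  dx <- prev[cand$trackPos, 1L] - detections$x[cand$detection]
  dy <- prev[cand$trackPos, 2L] - detections$y[cand$detection]
  cand$dist <- sqrt(dx^2 + dy^2)
  a1 <- prev[cand$trackPos, 3L]
  a2 <- detections$ellipticalArea[cand$detection]
  cand$ratio <- pmax(a1, a2) / pmin(a1, a2)
  cand <- cand[cand$dist <= params@tDis & cand$ratio <= params@tSize, ,
               drop = FALSE]
  ids <- vapply(activeTracks, `[[`, integer(1L), "id")
  cand <- cand[order(cand$dist, cand$ratio, ids[cand$trackPos],
                     cand$detection), , drop = FALSE]
  usedT <- logical(nt); usedD <- logical(nd)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ti <- cand$trackPos[k]; di <- cand$detection[k]
    if (!usedT[ti] && !usedD[di]) {
      keep[k] <- TRUE; usedT[ti] <- TRUE; usedD[di] <- TRUE
    }
  }
  m <- cand[keep, c("trackPos", "detection"), drop = FALSE]
  rownames(m) <- NULL
  list(matches = m, unmatchedTracks = which(!usedT),
       unmatchedDetections = which(!usedD))
}

#' Advance the track set by one sampled frame
#'
#' Matched tracks are extended with their detection; unmatched active tracks
#' are marked lost and frozen (kept for reporting, never re-matched — a
#' re-entering sperm starts a new track); unmatched detections open new
#' tracks with fresh, monotonically increasing ids.
#'
#' @param trackSet a \linkS4class{TrackSet}.
#' @param detections detections of the current sampled frame.
#' @param frameIndex the sampled frame number.
#' @param params a \linkS4class{TrackingParams}.
#' @return the updated \linkS4class{TrackSet}.
#' @export
stepTracks <- function(trackSet, detections, frameIndex, params) {
  tracks <- trackSet@tracks
  activePos <- which(vapply(tracks, `[[`, character(1L), "status") ==
                     "active")
  res <- associateDetections(tracks[activePos], detections, params)
  for (k in seq_len(nrow(res$matches))) {
    p <- activePos[res$matches$trackPos[k]]
    d <- res$matches$detection[k]
    tracks[[p]]$frames <- c(tracks[[p]]$frames, as.integer(frameIndex))
    tracks[[p]]$x <- c(tracks[[p]]$x, detections$x[d])
    tracks[[p]]$y <- c(tracks[[p]]$y, detections$y[d])
    tracks[[p]]$area <- c(tracks[[p]]$area, detections$ellipticalArea[d])
  }
  for (p in activePos[res$unmatchedTracks]) tracks[[p]]$status <- "lost"
  nid <- trackSet@nextId
  for (d in res$unmatchedDetections) {
    tracks[[length(tracks) + 1L]] <- list(id = nid,
      frames = as.integer(frameIndex), x = detections$x[d],
      y = detections$y[d], area = detections$ellipticalArea[d],
      status = "active")
    nid <- nid + 1L
  }
  initialize(trackSet, tracks = tracks, nextId = nid)
}

#' Run the full detection-and-tracking pipeline on a video
#'
#' Stage 1 and stage 2 composed: the adaptive mixture background model
#' consumes every frame; on every \code{stride}-th frame after the burn-in
#' the foreground mask is cleaned, sperm heads are detected by moments and
#' the elliptical-area rule, and detections are associated to tracks by the
#' distance and size-similarity gates. When \code{params@bgt} is NA the
#' background ratio is first optimized automatically on the burn-in prefix.
#' Fully deterministic.
#'
#' @param fseq a \linkS4class{FrameSequence}.
#' @param bgParams a \linkS4class{BackgroundParams}.
#' @param morphParams a \linkS4class{MorphologyParams}.
#' @param trackParams a \linkS4class{TrackingParams}.
#' @param minArea detection minimum elliptical area (px^2).
#' @param axisConvention axis convention for the area rule.
#' @return list with \code{tracks} (a \linkS4class{TrackSet}), \code{table}
#'   (the flat track table, see \code{\link{trackTable}}) and \code{bgt}
#'   (the background ratio actually used).
#' @export
trackVideo <- function(fseq, bgParams = backgroundParams(),
    morphParams = morphologyParams(), trackParams = trackingParams(),
    minArea = 150, axisConvention = "semi") {
  stopifnot(is(fseq, "FrameSequence"))
  nf <- nFrames(fseq)
  if (nf < bgParams@burnInFrames + 1L)
    stop("video shorter than burnInFrames + 1")
  if (is.na(bgParams@bgt))
    bgParams <- optimizeBackgroundThreshold(fseq, bgParams, morphParams,
                                            minArea)
  sampled <- seq(bgParams@burnInFrames + 1L, nf, by = trackParams@stride)
  ts <- new("TrackSet", tracks = list(), fps = fps(fseq),
            pixelScaleUm = pixelScaleUm(fseq), stride = trackParams@stride,
            nextId = 1L)
  state <- initMixture(fseq@frames[[1L]], bgParams)
  for (t in 2:nf) {
    res <- updateAndClassify(state, fseq@frames[[t]], bgParams)
    state <- res$state
    if (t %in% sampled) {
      det <- detectFrame(res$mask, morphParams, minArea, t, axisConvention)
      ts <- stepTracks(ts, det, t, trackParams)
    }
  }
  list(tracks = ts, table = trackTable(ts), bgt = bgParams@bgt)
}

#' Flatten a TrackSet into a track table
#'
#' One row per observation: \code{track_id}, \code{frame}, \code{x},
#' \code{y}, \code{area}, and \code{velocity_um_s} (the step velocity from
#' the previous observation of the same track; NA on each track's first
#' observation).
#'
#' @param trackSet a \linkS4class{TrackSet}.
#' @return data.frame sorted by (track_id, frame).
#' @export
trackTable <- function(trackSet) {
  stopifnot(is(trackSet, "TrackSet"))
  rows <- lapply(trackSet@tracks, function(trk) {
    n <- length(trk$frames)
    v <- rep(NA_real_, n)
    if (n >= 2L) for (k in 2:n)
      v[k] <- stepVelocity(c(trk$x[k - 1L], trk$y[k - 1L]),
                           c(trk$x[k], trk$y[k]),
                           stride = trk$frames[k] - trk$frames[k - 1L],
                           fps = trackSet@fps,
                           pixelScaleUm = trackSet@pixelScaleUm)
    data.frame(track_id = trk$id, frame = trk$frames, x = trk$x, y = trk$y,
               area = trk$area, velocity_um_s = v)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), area = numeric(0), velocity_um_s = numeric(0))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
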