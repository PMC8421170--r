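mkTrack <- function(id, x, y, area, frame = 10L, status = "active") {
  list(id = id, frames = as.integer(frame), x = x, y = y, area = area,
       status = status)
}

mkDet <- function(x, y, area, frame = 20L) {
  data.frame(frame = rep(as.integer(frame), length(x)), x = x, y = y,
             ellipticalArea = area, pixelArea = area)
}

emptyTrackSet <- function(stride = 10L)
  new("TrackSet", tracks = list(), fps = 50, pixelScaleUm = 0.2,
      stride = as.integer(stride), nextId = 1L)

test_that("euclideanDistance is the plain norm", {
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(c(2, 7), c(2, 7)), 0)
})

test_that("sizeSimilarity is a symmetric ratio gate at tSize", {
  expect_identical(sizeSimilarity(120, 100), 1L)   # ratio exactly 1.2
  expect_identical(sizeSimilarity(100, 120), 1L)   # symmetric
  expect_identical(sizeSimilarity(100, 100), 1L)
  expect_identical(sizeSimilarity(200, 100), 0L)
  expect_error(sizeSimilarity(0, 10), "positive")
})

test_that("association respects both gates, inclusively", {
  p <- trackingParams()
  trk <- list(mkTrack(1L, 0, 0, 100))
  # within both gates
  r <- associateDetections(trk, mkDet(3, 4, 100), p)
  expect_identical(nrow(r$matches), 1L)
  # distance exactly 125 passes
  r <- associateDetections(trk, mkDet(125, 0, 100), p)
  expect_identical(nrow(r$matches), 1L)
  # distance 200: both sides unmatched
  r <- associateDetections(trk, mkDet(200, 0, 100), p)
  expect_identical(nrow(r$matches), 0L)
  expect_identical(r$unmatchedTracks, 1L)
  expect_identical(r$unmatchedDetections, 1L)
  # size ratio above 1.2 blocks an otherwise close pair
  r <- associateDetections(trk, mkDet(1, 0, 130), p)
  expect_identical(nrow(r$matches), 0L)
})

test_that("greedy assignment resolves competing candidates by distance", {
  p <- trackingParams()
  trks <- list(mkTrack(1L, 0, 0, 100), mkTrack(2L, 10, 0, 100))
  dets <- mkDet(c(1, 9), c(0, 0), c(100, 100))
  r <- associateDetections(trks, dets, p)
  got <- r$matches[order(r$matches$trackPos), ]
  expect_equal(got$trackPos, c(1L, 2L))
  expect_equal(got$detection, c(1L, 2L))
})

test_that("greedy association equals exhaustive matching when separated", {
  set.seed(53)
  p <- trackingParams(tDis = 30, tSize = 1.2)
  gate <- 30
  for (rep in 1:20) {
    nt <- sample(2:4, 1L); nd <- sample(2:4, 1L)
    # place track anchors > 2*gate apart, detections near some anchors
    anchors <- matrix(0, 0, 2)
    while (nrow(anchors) < max(nt, nd)) {
      cand <- runif(2, 0, 500)
      if (!nrow(anchors) ||
          min(sqrt(rowSums((anchors - rep(cand, each = nrow(anchors)))^2))) >
            2 * gate + 1)
        anchors <- rbind(anchors, cand)
    }
    tXY <- anchors[seq_len(nt), , drop = FALSE]
    dXY <- anchors[seq_len(nd), , drop = FALSE] +
      matrix(runif(2 * nd, -10, 10), nd, 2)
    tA <- runif(nt, 150, 170); dA <- runif(nd, 150, 170)
    trks <- lapply(seq_len(nt), function(i)
      mkTrack(i, tXY[i, 1L], tXY[i, 2L], tA[i]))
    dets <- mkDet(dXY[, 1L], dXY[, 2L], dA)
    r <- associateDetections(trks, dets, p)
    oracle <- exhaustiveMatch(tXY, tA, dXY, dA, p@tDis, p@tSize)
    got <- integer(nt)
    got[r$matches$trackPos] <- r$matches$detection
    expect_identical(got, oracle)
  }
})

test_that("stepTracks extends, loses and creates tracks deterministically", {
  p <- trackingParams()
  ts <- emptyTrackSet()
  ts <- stepTracks(ts, mkDet(c(10, 300), c(10, 200), c(160, 160), 31L), 31L, p)
  expect_identical(length(ts@tracks), 2L)
  # one object moves, the other disappears
  ts <- stepTracks(ts, mkDet(25, 20, 162, 41L), 41L, p)
  st <- vapply(ts@tracks, `[[`, character(1L), "status")
  expect_identical(sum(st == "lost"), 1L)
  expect_identical(length(ts@tracks), 2L)      # no new ids for a lost object
  # three fresh detections appear far away: three new tracks
  ts <- stepTracks(ts, mkDet(c(400, 500, 600), c(50, 60, 70),
                             c(160, 160, 160), 51L), 51L, p)
  expect_identical(length(ts@tracks), 5L)
  ids <- vapply(ts@tracks, `[[`, integer(1L), "id")
  expect_identical(ids, 1:5)                   # ids increase monotonically
  # empty detection set: every active track is lost
  ts <- stepTracks(ts, mkDet(numeric(0), numeric(0), numeric(0), 61L), 61L, p)
  st <- vapply(ts@tracks, `[[`, character(1L), "status")
  expect_true(all(st == "lost"))
  # lost tracks are never resurrected
  ts2 <- stepTracks(ts, mkDet(25, 20, 162, 71L), 71L, p)
  expect_identical(length(ts2@tracks), 6L)
})

test_that("trackVideo recovers every object on a clean synthetic video", {
  init <- data.frame(x = c(50, 270), y = c(50, 150),
                     speed = c(2, 3), heading = c(0.2, pi - 0.2))
  cfg <- synthConfig(width = 320L, height = 200L, nFrames = 80L,
                     nMotile = 2L, nImmotile = 1L, nDebris = 3L,
                     border = "reflect", motileInit = init, seed = 17L)
  out <- generateVideo(cfg)
  res <- trackVideo(out$frames, backgroundParams(burnInFrames = 20L))
  expect_identical(length(res$tracks@tracks), 2L)
  sampled <- seq(21L, 80L, by = 10L)
  for (trk in res$tracks@tracks)
    expect_identical(trk$frames, sampled)
  # gate soundness: every stored step satisfies both gates by construction
  for (trk in res$tracks@tracks) {
    n <- length(trk$frames)
    d <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
    expect_true(all(d <= 125))
    ratio <- pmax(trk$area[-1], trk$area[-n]) /
             pmin(trk$area[-1], trk$area[-n])
    expect_true(all(ratio <= 1.2))
  }
  # recovered centroids sit on the ground-truth positions (< 2 px RMS)
  gt <- groundTruthTable(out$groundTruth)
  for (trk in res$tracks@tracks) {
    g <- gt[gt$class == "motile", ]
    first <- g[g$frame == trk$frames[1L], ]
    best <- first$id[which.min((first$x - trk$x[1L])^2 +
                               (first$y - trk$y[1L])^2)]
    sub <- g[g$id == best & g$frame %in% trk$frames, ]
    expect_identical(nrow(sub), length(trk$frames))
    rms <- sqrt(mean((sub$x - trk$x)^2 + (sub$y - trk$y)^2))
    expect_lt(rms, 2)
  }
})

test_that("a static scene yields zero tracks", {
  cfg <- synthConfig(width = 120L, height = 90L, nFrames = 40L, nMotile = 0L,
                     nImmotile = 2L, nDebris = 4L, seed = 19L)
  fs <- generateVideo(cfg)$frames
  res <- trackVideo(fs, backgroundParams(bgt = 0.5, burnInFrames = 20L))
  expect_identical(length(res$tracks@tracks), 0L)
  expect_identical(nrow(res$table), 0L)
})

test_that("the whole pipeline is deterministic (byte-identical tables)", {
  cfg <- synthConfig(width = 220L, height = 160L, nFrames = 45L, nMotile = 1L,
                     nImmotile = 1L, nDebris = 2L, speedRange = c(2, 3),
                     border = "reflect", seed = 23L)
  fs <- generateVideo(cfg)$frames
  p <- backgroundParams(burnInFrames = 15L)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeTracks(trackVideo(fs, p)$table, f1)
  writeTracks(trackVideo(fs, p)$table, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the stride-scaling flag rescales the distance gate", {
  p <- trackingParams(stride = 5L, scaleGateWithStride = TRUE)
  expect_equal(p@tDis, 62.5)
  p2 <- trackingParams(stride = 5L)
  expect_equal(p2@tDis, 125)
})
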