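#' @include AllClasses.R
NULL

## Evaluate expr with a private, seeded RNG stream, restoring the caller's
## RNG state afterwards so the generator is reproducible and side-effect free.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configure the synthetic microscopy-video generator
#'
#' Builds a validated \linkS4class{SynthConfig}. The generator emulates what
#' the tracking pipeline actually relies on in real CASA recordings: bright
#' elliptical sperm heads moving over a dark background, immotile cells,
#' sub-threshold debris, and additive Gaussian sensor noise. Defaults mirror a
#' typical acquisition (640x480 frames at 50 fps).
#'
#' @param width,height frame size in pixels.
#' @param nFrames number of frames to render.
#' @param fps frame rate in frames/second.
#' @param nMotile,nImmotile,nDebris object counts.
#' @param headSemiAxesRange min/max head ellipse semi-axes (px).
#' @param speedRange min/max motile speed (px/frame).
#' @param debrisAreaMax maximum debris area (px^2), strictly below the
#'   150 px^2 detection rule.
#' @param backgroundLevel,headLevel 8-bit intensities.
#' @param noiseSigma sensor noise standard deviation (intensity units).
#' @param border \code{"exit"} or \code{"reflect"} at frame borders.
#' @param headingJitterSd per-frame heading jitter in radians (0 = straight
#'   lines).
#' @param illuminationGradient add a mild horizontal illumination ramp.
#' @param motileInit optional data.frame (x, y, speed, heading) fixing the
#'   motile objects' initial states instead of drawing them.
#' @param seed RNG seed.
#' @return a \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(width = 160, height = 120, nFrames = 40, nMotile = 2,
#'                    nImmotile = 1, nDebris = 3, seed = 7)
#' @export
synthConfig <- function(width = 640L, height = 480L, nFrames = 300L,
    fps = 50, nMotile = 5L, nImmotile = 3L, nDebris = 20L,
    headSemiAxesRange = c(8, 11), speedRange = c(1, 4), debrisAreaMax = 30,
    backgroundLevel = 60, headLevel = 200, noiseSigma = 5,
    border = c("exit", "reflect"), headingJitterSd = 0,
    illuminationGradient = FALSE, motileInit = NULL, seed = 1L) {
  border <- match.arg(border)
  if (is.null(motileInit))
    motileInit <- data.frame(x = numeric(0), y = numeric(0),
                             speed = numeric(0), heading = numeric(0))
  new("SynthConfig", width = as.integer(width), height = as.integer(height),
      nFrames = as.integer(nFrames), fps = as.numeric(fps),
      nMotile = as.integer(nMotile), nImmotile = as.integer(nImmotile),
      nDebris = as.integer(nDebris),
      headSemiAxesRange = as.numeric(headSemiAxesRange),
      speedRange = as.numeric(speedRange),
      debrisAreaMax = as.numeric(debrisAreaMax),
      backgroundLevel = as.numeric(backgroundLevel),
      headLevel = as.numeric(headLevel), noiseSigma = as.numeric(noiseSigma),
      border = border, headingJitterSd = as.numeric(headingJitterSd),
      illuminationGradient = illuminationGradient,
      motileInit = motileInit, seed = as.integer(seed))
}

## Linear indices of the pixels of a (possibly rotated) filled ellipse with
## continuous centre (cx, cy) in 0-based coordinates, clipped to the frame.
rasterEllipse <- function(cx, cy, a, b, theta, nr, nc) {
  c1 <- max(1L, floor(cx - a) + 1L); c2 <- min(nc, ceiling(cx + a) + 1L)
  r1 <- max(1L, floor(cy - a) + 1L); r2 <- min(nr, ceiling(cy + a) + 1L)
  if (c1 > c2 || r1 > r2) return(integer(0))
  cols <- c1:c2; rows <- r1:r2
  dx <- rep(cols - 1 - cx, each = length(rows))
  dy <- rep(rows - 1 - cy, times = length(cols))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ridx <- rep(rows, times = length(cols))
  cidx <- rep(cols, each = length(rows))
  (cidx[inside] - 1L) * nr + ridx[inside]
}

## Rejection-sample a position at least minSep away from `taken` (2-col
## matrix) and margin away from borders.
placeObject <- function(w, h, margin, taken, minSep, maxTries = 20000L) {
  for (i in seq_len(maxTries)) {
    p <- c(runif(1, margin, w - 1 - margin), runif(1, margin, h - 1 - margin))
    if (!nrow(taken) ||
        min(sqrt((taken[, 1] - p[1])^2 + (taken[, 2] - p[2])^2)) >= minSep)
      return(p)
  }
  stop("could not place object: scene too crowded for the requested counts")
}

#' Generate a ground-truthed synthetic sperm-motility video
#'
#' Renders \code{nFrames} grayscale frames containing motile sperm heads
#' (filled ellipses moving along straight constant-speed paths, oriented
#' along their heading), immotile heads, small static debris blobs, and
#' additive clipped Gaussian noise. Objects never overlap: static objects are
#' placed away from every motile trajectory, matching the scope of the
#' tracker (no collision handling). The returned ground truth records the
#' exact continuous centre and rendered pixel area of every object in every
#' frame in which it appears. Identical configurations (including the seed)
#' give bit-identical frames and ground truth.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param pixelScaleUm micrometres per pixel recorded in the output
#'   \linkS4class{FrameSequence} (default 0.2).
#' @return list with elements \code{frames} (a \linkS4class{FrameSequence})
#'   and \code{groundTruth} (a \linkS4class{GroundTruth}).
#' @examples
#' out <- generateVideo(synthConfig(width = 160, height = 120, nFrames = 30,
#'                                  nMotile = 2, nImmotile = 1, nDebris = 2,
#'                                  seed = 3))
#' out$frames
#' out$groundTruth
#' @export
generateVideo <- function(config, pixelScaleUm = 0.2) {
  validObject(config)
  withSeed(config@seed, {
    w <- config@width; h <- config@height; nf <- config@nFrames
    nr <- h; nc <- w
    axr <- config@headSemiAxesRange
    margin <- axr[2L] + 2

    ## --- motile objects: initial states and full kinematics -------------
    nm <- config@nMotile
    if (nrow(config@motileInit)) {
      if (nrow(config@motileInit) != nm)
        stop("motileInit must have one row per motile object")
      mx <- config@motileInit$x; my <- config@motileInit$y
      spd <- config@motileInit$speed; hd <- config@motileInit$heading
    } else {
      mx <- my <- numeric(nm)
      taken <- matrix(numeric(0), 0, 2)
      for (i in seq_len(nm)) {
        p <- placeObject(w, h, margin, taken, 2 * axr[2L] + 6)
        mx[i] <- p[1]; my[i] <- p[2]; taken <- rbind(taken, p)
      }
      spd <- runif(nm, config@speedRange[1L], config@speedRange[2L])
      hd <- runif(nm, 0, 2 * pi)
    }
    ma <- if (nm) runif(nm, axr[1L], axr[2L]) else numeric(0)
    mb <- if (nm) runif(nm, axr[1L], pmax(axr[1L], ma * 0.8)) else numeric(0)

    ## positions for every frame (nf x nm); straight lines with optional
    ## heading jitter; reflecting or exiting borders
    px <- matrix(NA_real_, nf, max(nm, 1L))
    py <- matrix(NA_real_, nf, max(nm, 1L))
    th <- matrix(NA_real_, nf, max(nm, 1L))
    if (nm) {
      x <- mx; y <- my; ang <- hd
      lo <- margin; hix <- w - 1 - margin; hiy <- h - 1 - margin
      for (t in seq_len(nf)) {
        px[t, ] <- x; py[t, ] <- y; th[t, ] <- ang
        if (config@headingJitterSd > 0)
          ang <- ang + rnorm(nm, 0, config@headingJitterSd)
        x <- x + spd * cos(ang)
        y <- y + spd * sin(ang)
        if (config@border == "reflect") {
          for (i in seq_len(nm)) {
            vx <- cos(ang[i]); vy <- sin(ang[i])
            if (x[i] < lo) { x[i] <- 2 * lo - x[i]; vx <- -vx }
            if (x[i] > hix) { x[i] <- 2 * hix - x[i]; vx <- -vx }
            if (y[i] < lo) { y[i] <- 2 * lo - y[i]; vy <- -vy }
            if (y[i] > hiy) { y[i] <- 2 * hiy - y[i]; vy <- -vy }
            ang[i] <- atan2(vy, vx)
          }
        }
      }
    }

    ## --- static objects, placed clear of every motile position ----------
    occupied <- if (nm)
      cbind(as.vector(px), as.vector(py)) else matrix(numeric(0), 0, 2)
    occupied <- occupied[stats::complete.cases(occupied), , drop = FALSE]
    ni <- config@nImmotile; nd <- config@nDebris
    statXY <- matrix(numeric(0), 0, 2)
    sep <- 2 * axr[2L] + 6
    for (i in seq_len(ni + nd)) {
      p <- placeObject(w, h, margin, rbind(occupied, statXY), sep)
      statXY <- rbind(statXY, p)
    }
    ia <- if (ni) runif(ni, axr[1L], axr[2L]) else numeric(0)
    ib <- if (ni) runif(ni, axr[1L], pmax(axr[1L], ia * 0.8)) else numeric(0)
    ith <- if (ni) runif(ni, 0, 2 * pi) else numeric(0)
    rmax <- sqrt(config@debrisAreaMax / pi)
    dr <- if (nd) runif(nd, min(1.5, rmax), rmax) else numeric(0)

    ## pre-rasterize the static objects once
    statIdx <- vector("list", ni + nd)
    if (ni) for (i in seq_len(ni))
      statIdx[[i]] <- rasterEllipse(statXY[i, 1], statXY[i, 2],
                                    ia[i], ib[i], ith[i], nr, nc)
    if (nd) for (i in seq_len(nd))
      statIdx[[ni + i]] <- rasterEllipse(statXY[ni + i, 1], statXY[ni + i, 2],
                                         dr[i], dr[i], 0, nr, nc)

    ## --- render frames and accumulate ground truth ----------------------
    base <- matrix(config@backgroundLevel, nr, nc)
    if (config@illuminationGradient)
      base <- base + matrix(rep(seq(0, 15, length.out = nc), each = nr),
                            nr, nc)
    ids <- list(motile = seq_len(nm),
                immotile = nm + seq_len(ni),
                debris = nm + ni + seq_len(nd))
    frameList <- vector("list", nf)
    gtRows <- vector("list", nf)
    for (t in seq_len(nf)) {
      fr <- base
      rows <- list()
      if (nm) for (i in seq_len(nm)) {
        idx <- rasterEllipse(px[t, i], py[t, i], ma[i], mb[i], th[t, i],
                             nr, nc)
        if (length(idx)) {
          fr[idx] <- config@headLevel
          rows[[length(rows) + 1L]] <- data.frame(id = ids$motile[i],
            class = "motile", frame = t, x = px[t, i], y = py[t, i],
            area = length(idx))
        }
      }
      for (i in seq_len(ni + nd)) {
        idx <- statIdx[[i]]
        fr[idx] <- config@headLevel
        rows[[length(rows) + 1L]] <- data.frame(
          id = nm + i,
          class = if (i <= ni) "immotile" else "debris",
          frame = t, x = statXY[i, 1], y = statXY[i, 2], area = length(idx))
      }
      if (config@noiseSigma > 0)
        fr <- fr + matrix(rnorm(nr * nc, 0, config@noiseSigma), nr, nc)
      fr[fr < 0] <- 0
      fr[fr > 255] <- 255
      fr <- round(fr)
      storage.mode(fr) <- "integer"
      frameList[[t]] <- fr
      gtRows[[t]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    gt <- do.call(rbind, gtRows)
    if (is.null(gt))
      gt <- data.frame(id = integer(0), class = character(0),
                       frame = integer(0), x = numeric(0), y = numeric(0),
                       area = integer(0))
    gt <- gt[order(gt$id, gt$frame), , drop = FALSE]
    rownames(gt) <- NULL
    list(frames = new("FrameSequence", frames = frameList, fps = config@fps,
                      pixelScaleUm = pixelScaleUm),
         groundTruth = new("GroundTruth", tracks = gt, fps = config@fps))
  })
}

#' Write / read ground truth as JSON
#'
#' Serializes a \linkS4class{GroundTruth} to the documented schema:
#' \code{\{fps, tracks: [\{id, class, frames: [\{frame, x, y, area\}]\}]\}}
#' with 0-based pixel-centre coordinates (x = column, y = row) and 1-based
#' frame numbers. \code{readGroundTruth(writeGroundTruth(gt, f))}
#' reconstructs \code{gt} exactly; repeated writes of the same object are
#' byte-identical.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param path output (input) file path.
#' @return \code{writeGroundTruth}: \code{path}, invisibly.
#' @export
writeGroundTruth <- function(gt, path) {
  stopifnot(is(gt, "GroundTruth"))
  tr <- gt@tracks
  ids <- unique(tr$id)
  trackList <- lapply(ids, function(i) {
    sub <- tr[tr$id == i, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    list(id = i, class = sub$class[1L],
         frames = lapply(seq_len(nrow(sub)), function(k)
           list(frame = sub$frame[k], x = sub$x[k], y = sub$y[k],
                area = sub$area[k])))
  })
  obj <- list(fps = gt@fps, tracks = trackList)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @return \code{readGroundTruth}: the reconstructed
#'   \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$tracks, function(trk) {
    fr <- trk$frames
    if (!length(fr))
      return(NULL)
    data.frame(id = as.integer(trk$id), class = as.character(trk$class),
               frame = vapply(fr, function(e) as.integer(e$frame), 1L),
               x = vapply(fr, function(e) as.numeric(e$x), 1),
               y = vapply(fr, function(e) as.numeric(e$y), 1),
               area = vapply(fr, function(e) as.integer(e$area), 1L))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  tr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), class = character(0), frame = integer(0),
               x = numeric(0), y = numeric(0), area = integer(0))
  tr <- tr[order(tr$id, tr$frame), , drop = FALSE]
  rownames(tr) <- NULL
  new("GroundTruth", tracks = tr, fps = as.numeric(obj$fps))
}
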