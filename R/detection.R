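#' @include AllClasses.R
NULL

#' Morphology parameters
#'
#' Structuring element (SE) used to clean foreground masks. The disk SE
#' yields the most uniform sperm-head blobs; line and square SEs are kept for
#' comparison experiments.
#'
#' @param seShape \code{"disk"} (default), \code{"line"} or \code{"square"}.
#' @param seRadius SE radius in pixels (the SE spans \code{2*seRadius + 1}).
#' @return a \linkS4class{MorphologyParams}.
#' @export
morphologyParams <- function(seShape = c("disk", "line", "square"),
                             seRadius = 3L) {
  new("MorphologyParams", seShape = match.arg(seShape),
      seRadius = as.integer(seRadius))
}

makeSE <- function(params) {
  size <- 2L * params@seRadius + 1L
  shape <- switch(params@seShape, disk = "disc", line = "line",
                  square = "box")
  EBImage::makeBrush(size, shape = shape)
}

#' Morphologically clean a foreground mask
#'
#' Applies an opening (erosion then dilation, removing specks smaller than
#' the SE) followed by a closing (dilation then erosion, filling small holes)
#' with the same structuring element.
#'
#' @param mask binary matrix (0/1).
#' @param params a \linkS4class{MorphologyParams}.
#' @return binary integer matrix of the same shape.
#' @export
cleanMask <- function(mask, params = morphologyParams()) {
  stopifnot(is.matrix(mask))
  kern <- makeSE(params)
  out <- EBImage::closing(EBImage::opening(mask, kern), kern)
  m <- matrix(as.integer(EBImage::imageData(out) > 0.5), nrow(mask),
              ncol(mask))
  m
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
## diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # / diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    findRoot <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[k, 1L]); rb <- findRoot(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), findRoot, 1L)
    compact <- match(root, sort(unique(root)))
    lab[lab > 0L] <- compact[lab[lab > 0L]]
  }
  lab
}

#' Label connected foreground regions and compute their moments
#'
#' Finds 8-connected components of a binary mask and computes, per region,
#' the zero- and first-order moments (\code{n00} = pixel count, \code{n10} =
#' sum of x, \code{n01} = sum of y), the centroid \code{(n10/n00, n01/n00)},
#' and the semi-axes of the ellipse whose second central moments match the
#' region's (with the 1/12 pixel-integration term on the diagonal so that
#' even a single pixel has positive axes).
#'
#' @param mask binary matrix (0/1).
#' @return data.frame with one row per region: \code{label}, \code{n00},
#'   \code{n10}, \code{n01}, \code{xc}, \code{yc}, \code{a} (semi-major),
#'   \code{b} (semi-minor). Coordinates are 0-based (x = column, y = row).
#'   Empty mask gives zero rows.
#' @export
labelRegions <- function(mask) {
  stopifnot(is.matrix(mask))
  empty <- data.frame(label = integer(0), n00 = numeric(0), n10 = numeric(0),
                      n01 = numeric(0), xc = numeric(0), yc = numeric(0),
                      a = numeric(0), b = numeric(0))
  if (!any(mask != 0)) return(empty)
  lab <- label8(mask)
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  x <- as.numeric((idx - 1L) %/% nr)   # 0-based column
  y <- as.numeric((idx - 1L) %% nr)    # 0-based row
  n00 <- as.numeric(tabulate(l))
  s <- rowsum(cbind(x, y, x * x, y * y, x * y), l)
  n10 <- s[, 1L]; n01 <- s[, 2L]
  xc <- n10 / n00; yc <- n01 / n00
  mu20 <- (s[, 3L] - n00 * xc^2) / n00 + 1 / 12
  mu02 <- (s[, 4L] - n00 * yc^2) / n00 + 1 / 12
  mu11 <- (s[, 5L] - n00 * xc * yc) / n00
  half <- (mu20 + mu02) / 2
  spread <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- half + spread
  l2 <- pmax(half - spread, 1e-12)
  data.frame(label = seq_along(n00), n00 = n00, n10 = n10, n01 = n01,
             xc = xc, yc = yc, a = 2 * sqrt(l1), b = 2 * sqrt(l2))
}

#' Elliptical area
#'
#' \eqn{\pi a b}: the area of an ellipse with semi-axes a and b. The area
#' rule of the detection stage plugs the moment-ellipse SEMI-axes into this
#' formula by default; the \code{"full"} axis convention of
#' \code{\link{filterDetections}} plugs in full axis lengths instead (which
#' quadruples the value and is kept only for comparison).
#'
#' @param a,b semi-major and semi-minor axes in pixels (> 0).
#' @return area in pixel^2.
#' @examples
#' ellipseArea(5, 3)    # 15 * pi
#' @export
ellipseArea <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("axes must be positive")
  pi * a * b
}

#' Filter labeled regions down to sperm-head detections
#'
#' Keeps regions whose elliptical area is at least \code{minArea} (the
#' 150 px^2 rule: smaller blobs are debris). Survivors are ordered by
#' centroid (y, then x) for determinism.
#'
#' @param regions data.frame from \code{\link{labelRegions}}.
#' @param minArea minimum elliptical area in px^2 (inclusive).
#' @param frameIndex frame number stored with the detections.
#' @param axisConvention passed to \code{\link{ellipseArea}}; with
#'   \code{"full"} the region's moment semi-axes are doubled first.
#' @return data.frame with columns \code{frame}, \code{x}, \code{y},
#'   \code{ellipticalArea}, \code{pixelArea}.
#' @export
filterDetections <- function(regions, minArea = 150, frameIndex = NA_integer_,
                             axisConvention = c("semi", "full")) {
  axisConvention <- match.arg(axisConvention)
  if (!nrow(regions))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      ellipticalArea = numeric(0), pixelArea = numeric(0)))
  ea <- if (axisConvention == "semi") ellipseArea(regions$a, regions$b)
        else ellipseArea(2 * regions$a, 2 * regions$b)
  keep <- ea >= minArea
  out <- data.frame(frame = rep(as.integer(frameIndex), sum(keep)),
                    x = regions$xc[keep],
                    y = regions$yc[keep], ellipticalArea = ea[keep],
                    pixelArea = regions$n00[keep])
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect sperm heads in one foreground mask
#'
#' Convenience composition of \code{\link{cleanMask}},
#' \code{\link{labelRegions}} and \code{\link{filterDetections}}.
#'
#' @param mask binary foreground matrix.
#' @param morphParams a \linkS4class{MorphologyParams}.
#' @param minArea minimum elliptical area (px^2).
#' @param frameIndex frame number stored with the detections.
#' @param axisConvention axis convention for the elliptical-area rule.
#' @return detections data.frame (see \code{\link{filterDetections}}).
#' @export
detectFrame <- function(mask, morphParams = morphologyParams(),
                        minArea = 150, frameIndex = NA_integer_,
                        axisConvention = "semi") {
  filterDetections(labelRegions(cleanMask(mask, morphParams)),
                   minArea = minArea, frameIndex = frameIndex,
                   axisConvention = axisConvention)
}
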