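#' @include AllClasses.R
NULL

#' Background model parameters
#'
#' Parameters of the per-pixel adaptive Gaussian mixture. Each pixel carries
#' \code{K} Gaussians (weight, mean, variance) kept sorted by
#' \eqn{\pi/\sqrt{\Sigma}}; the first components whose cumulative weight
#' reaches the background ratio \code{bgt} model the background, the rest
#' model transient foreground (moving sperm heads).
#'
#' @param bgt background ratio threshold in (0, 1], or \code{"auto"} /
#'   \code{NA} to optimize it per sample with
#'   \code{\link{optimizeBackgroundThreshold}}.
#' @param K Gaussians per pixel.
#' @param alpha learning rate for the component weights.
#' @param lambda match threshold in standard deviations: a pixel value
#'   matches a component when \eqn{|x-\mu| \le \lambda\sqrt{\Sigma}}.
#' @param initialVariance variance assigned to newly created components.
#' @param varianceFloor lower bound on component variances.
#' @param weightFloor weight assigned to replacement components.
#' @param adaptiveStart use a 1/t learning-rate schedule during the first
#'   \code{1/alpha} frames (standard start-up handling for adaptive mixture
#'   models): the bootstrap frame initializes every pixel's first component,
#'   so without it, background uncovered behind initially present objects
#'   would stay misclassified as foreground ("ghost trails") for tens of
#'   frames.
#' @param burnInFrames frames consumed to learn the background before
#'   detections are trusted.
#' @param grid candidate BG_T grid for the automatic optimizer (10\% steps
#'   from 10\% to 100\%).
#' @return a \linkS4class{BackgroundParams}.
#' @export
backgroundParams <- function(bgt = NA, K = 3L, alpha = 0.05, lambda = 2.5,
    initialVariance = 225, varianceFloor = 4, weightFloor = 0.05,
    adaptiveStart = TRUE, burnInFrames = 30L, grid = seq(0.1, 1, by = 0.1)) {
  if (identical(bgt, "auto")) bgt <- NA
  new("BackgroundParams", bgt = as.numeric(bgt), K = as.integer(K),
      alpha = as.numeric(alpha), lambda = as.numeric(lambda),
      initialVariance = as.numeric(initialVariance),
      varianceFloor = as.numeric(varianceFloor),
      weightFloor = as.numeric(weightFloor),
      adaptiveStart = isTRUE(adaptiveStart),
      burnInFrames = as.integer(burnInFrames), grid = as.numeric(grid))
}

#' Univariate Gaussian density
#'
#' \eqn{(2\pi\Sigma)^{-1/2} \exp(-(x-\mu)^2 / (2\Sigma))}: the
#' one-dimensional specialization of the multivariate normal used to model
#' per-pixel intensity classes.
#'
#' @param x intensity value(s).
#' @param mu mean intensity.
#' @param sigma2 variance (> 0).
#' @return density value(s), strictly positive, maximal at \code{x == mu}.
#' @examples
#' gaussianDensity(0, 0, 1)        # 1/sqrt(2*pi)
#' @export
gaussianDensity <- function(x, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  exp(-0.5 * (x - mu)^2 / sigma2) / sqrt(2 * pi * sigma2)
}

#' Initialize the per-pixel mixture from the first frame
#'
#' Each pixel starts with one component centred at its observed intensity
#' (weight 1, variance \code{initialVariance}) plus \code{K - 1} zero-weight
#' placeholders. Deterministic.
#'
#' @param frame integer matrix (first video frame).
#' @param params a \linkS4class{BackgroundParams}.
#' @return a \linkS4class{MixtureState}.
#' @export
initMixture <- function(frame, params) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  n <- length(frame); K <- params@K
  x <- as.numeric(frame)
  W <- matrix(0, n, K); W[, 1L] <- 1
  M <- matrix(x, n, K)              # placeholders share the observed mean
  V <- matrix(params@initialVariance, n, K)
  new("MixtureState", weight = W, mean = M, var = V,
      dims = dim(frame), frameCount = 1L)
}

## Per-row ordering of the K components by weight/sqrt(var), descending,
## ties broken by column index. Returns an n x K matrix of column indices.
orderComponents <- function(W, V) {
  n <- nrow(W); K <- ncol(W)
  r <- W / sqrt(V)
  ord <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    ord[, k] <- max.col(r, ties.method = "first")
    r[cbind(seq_len(n), ord[, k])] <- -Inf
  }
  ord
}

#' Update the mixture with one frame and classify its pixels
#'
#' For every pixel: components are ranked by \eqn{\pi/\sqrt{\Sigma}} and the
#' background is the shortest prefix whose cumulative weight reaches the
#' background ratio \code{bgt}. The pixel matches the first ranked component
#' with \eqn{|x-\mu| \le \lambda\sqrt{\Sigma}}. Weights decay by
#' \eqn{\pi \leftarrow (1-\alpha)\pi} with \eqn{+\alpha} on the matched
#' component, whose mean and variance move toward the observation with rate
#' \eqn{\rho = \alpha \exp(-(x-\mu)^2/(2\Sigma))} (the match density scaled
#' by its own peak). Unmatched pixels replace their lowest-weight component
#' with a new Gaussian at the observed value. Weights are renormalized to
#' sum to 1. The pixel is foreground iff it matched no background component.
#'
#' @param state a \linkS4class{MixtureState}.
#' @param frame integer matrix of the same dimensions.
#' @param params a \linkS4class{BackgroundParams} with a concrete (non-NA)
#'   \code{bgt}.
#' @return list with elements \code{state} (updated
#'   \linkS4class{MixtureState}) and \code{mask} (binary foreground matrix).
#' @export
updateAndClassify <- function(state, frame, params) {
  if (!all(dim(frame) == state@dims))
    stop("frame dimensions do not match the mixture state")
  if (is.na(params@bgt))
    stop("bgt is NA; run optimizeBackgroundThreshold or set a value")
  n <- nrow(state@weight); K <- ncol(state@weight)
  x <- as.numeric(frame)
  W <- state@weight; M <- state@mean; V <- state@var
  rows <- seq_len(n)
  alpha <- if (params@adaptiveStart)
    max(params@alpha, 1 / (state@frameCount + 1)) else params@alpha

  ord <- orderComponents(W, V)
  matched <- abs(x - M) <= params@lambda * sqrt(V)

  ## first match in ranked order; background prefix by cumulative weight
  matchPos <- integer(n); matchIdx <- integer(n)
  remaining <- rep(TRUE, n)
  cumw <- numeric(n); B <- integer(n)
  for (k in seq_len(K)) {
    idx <- ord[, k]
    sel <- cbind(rows, idx)
    hit <- remaining & matched[sel]
    matchPos[hit] <- k
    matchIdx[hit] <- idx[hit]
    remaining <- remaining & !hit
    newBG <- B == 0L & (cumw + W[sel]) >= params@bgt
    cumw <- cumw + W[sel]
    B[newBG] <- k
  }
  B[B == 0L] <- K
  mask <- matrix(as.integer(matchPos == 0L | matchPos > B), state@dims[1L],
                 state@dims[2L])

  ## weight update
  W <- (1 - alpha) * W
  mi <- matchPos > 0L
  selM <- cbind(rows[mi], matchIdx[mi])
  W[selM] <- W[selM] + alpha

  ## matched component mean/variance update
  d <- x[mi] - M[selM]
  rho <- alpha * exp(-0.5 * d^2 / V[selM])
  M[selM] <- M[selM] + rho * d
  V[selM] <- pmax(params@varianceFloor, V[selM] + rho * (d^2 - V[selM]))

  ## unmatched pixels: replace the lowest-weight component
  ui <- rows[!mi]
  if (length(ui)) {
    low <- max.col(-W[ui, , drop = FALSE], ties.method = "first")
    selU <- cbind(ui, low)
    W[selU] <- params@weightFloor
    M[selU] <- x[ui]
    V[selU] <- params@initialVariance
  }
  W <- W / rowSums(W)

  st <- new("MixtureState", weight = W, mean = M, var = V,
            dims = state@dims, frameCount = state@frameCount + 1L)
  list(state = st, mask = mask)
}

## Train a fresh mixture over frames [1, nTrain] and return the foreground
## mask of frame nTrain + 1 (classification only; the state is not advanced
## past the returned frame unless advance = TRUE).
burnInAndClassify <- function(fseq, params, nTrain) {
  fr <- fseq@frames
  state <- initMixture(fr[[1L]], params)
  if (nTrain >= 2) for (t in 2:nTrain)
    state <- updateAndClassify(state, fr[[t]], params)$state
  updateAndClassify(state, fr[[nTrain + 1L]], params)
}

#' Optimize the background ratio threshold per sample
#'
#' Implements the automatic BG_T protocol: for each candidate value on the
#' grid (10\%..100\% in 10\% steps by default), a fresh mixture is trained on
#' the burn-in prefix of the video, the first post-burn-in frame is
#' classified, the mask is cleaned morphologically, and the number of valid
#' detections (elliptical area at or above \code{minArea}) is counted. The
#' BG_T attaining the highest count wins; ties go to the smallest value
#' (stricter foreground). The mixture update itself does not depend on BG_T,
#' so all grid values see an identically trained model, which makes the
#' search a pure threshold selection.
#'
#' @param fseq a \linkS4class{FrameSequence} with at least
#'   \code{burnInFrames + 1} frames.
#' @param params a \linkS4class{BackgroundParams} (its \code{bgt} is
#'   ignored and replaced).
#' @param morphParams a \linkS4class{MorphologyParams} for mask cleaning.
#' @param minArea detection minimum elliptical area (px^2).
#' @param verbose emit one message per grid value (BG_T, detection count).
#' @return the input \code{params} with \code{bgt} set to the winning grid
#'   value; the per-grid detection counts are attached as
#'   \code{attr(, "gridCounts")} (named numeric vector).
#' @export
optimizeBackgroundThreshold <- function(fseq, params,
    morphParams = morphologyParams(), minArea = 150, verbose = FALSE) {
  nb <- params@burnInFrames
  if (nFrames(fseq) < nb + 1L)
    stop("need at least burnInFrames + 1 frames to optimize BG_T")
  counts <- numeric(length(params@grid))
  for (g in seq_along(params@grid)) {
    p <- params
    p@bgt <- params@grid[g]
    res <- burnInAndClassify(fseq, p, nb)
    det <- filterDetections(labelRegions(cleanMask(res$mask, morphParams)),
                            minArea = minArea, frameIndex = nb + 1L)
    counts[g] <- nrow(det)
    if (verbose)
      message(sprintf("BG_T = %.2f: %d detections", params@grid[g],
                      counts[g]))
  }
  best <- which(counts == max(counts))[1L]   # smallest BG_T wins ties
  out <- params
  out@bgt <- params@grid[best]
  attr(out, "gridCounts") <- setNames(counts, sprintf("%.2f", params@grid))
  out
}
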